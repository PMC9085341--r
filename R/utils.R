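# Internal helpers shared across modules.

#' Cost component categories of the discharge abstract
#'
#' The eight cost categories recorded on the Chinese inpatient medical-record
#' homepage, in the fixed order used throughout the package.
#'
#' @return Character vector of category names.
#' @export
cost_categories <- function() {
  c("diagnosis", "drug", "comprehensive_service", "rehabilitation",
    "consumables", "treatment", "blood_products", "other")
}

# Column names holding the component amounts in a cohort data frame.
cost_columns <- function() paste0("cost_", cost_categories())

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stirling number of the second kind S(n, k): ways to partition n labelled
# items into k unlabelled nonempty blocks. Sizes here are tiny (n <= ~6).
stirling2 <- function(n, k) {
  if (k < 0 || k > n) return(0)
  if (k == 0) return(as.numeric(n == 0))
  s <- matrix(0, n + 1, k + 1)
  s[1, 1] <- 1
  for (i in seq_len(n)) {
    for (j in seq_len(min(i, k))) {
      s[i + 1, j + 1] <- j * s[i, j + 1] + s[i, j]
    }
  }
  s[n + 1, k + 1]
}

# Currency rounding: 2 decimals, R's round() is IEC half-to-even.
round_currency <- function(x) round(x, 2)

# Split a ";"-delimited code cell into a character vector (empty -> length 0).
split_codes <- function(x) {
  out <- strsplit(as.character(x), ";", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

join_codes <- function(lst) {
  vapply(lst, function(v) paste(v, collapse = ";"), character(1))
}

stop_input <- function(...) stop(..., call. = FALSE)
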