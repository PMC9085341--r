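# Discharge-abstract records: domain checks, delimited I/O, exclusion-criteria
# cleaning, comorbidity/complication (MCC/CC) severity and derived features.
#
# A cohort is a plain data.frame with one row per admission:
#   record_id        character, unique per admission
#   sex              "male" / "female"
#   age              integer years >= 0
#   allergy          logical
#   social_insurance logical
#   admission_route  "emergency" / "outpatient_other"
#   discharge_mode   "home" / "transfer" / "death" / "other"
#   admission_year   calendar year
#   los              integer days >= 1
#   primary_dx       diagnosis code
#   secondary_dx     ";"-separated diagnosis codes (may be blank)
#   procedures       ";"-separated procedure codes (may be blank)
#   total_cost       currency > 0
#   cost_<category>  eight component amounts >= 0 summing to total_cost

required_scalar_fields <- function() {
  c("record_id", "sex", "age", "allergy", "social_insurance",
    "admission_route", "discharge_mode", "admission_year", "los",
    "primary_dx", "total_cost", cost_columns())
}

sex_levels <- function() c("female", "male")
admission_levels <- function() c("outpatient_other", "emergency")
discharge_levels <- function() c("home", "transfer", "death", "other")
age_band_levels <- function() c("0-17", "18-65", ">65")
cc_levels <- function() c("NonCC", "CC", "MCC")

#' Validate a cohort data frame against the discharge-abstract contract
#'
#' Checks presence of required columns and, row by row, the record invariants:
#' categorical fields in their admissible sets, `los >= 1`, `total_cost > 0`,
#' nonnegative cost components, and the component sum matching `total_cost`
#' within `component_tol`.
#'
#' @param cohort Data frame of admissions.
#' @param component_tol Absolute tolerance (currency units) for the component
#'   sum check. Default 0.05 (half a fen above exact-cent agreement).
#' @return Data frame of problems with columns `row`, `field`, `issue`
#'   (zero rows when the cohort is clean).
#' @export
validate_cohort <- function(cohort, component_tol = 0.05) {
  missing_cols <- setdiff(c(required_scalar_fields(), "secondary_dx", "procedures"),
                          names(cohort))
  if (length(missing_cols) > 0) {
    stop_input("cohort is missing required column(s): ",
               paste(missing_cols, collapse = ", "))
  }
  problems <- list()
  note <- function(rows, field, issue) {
    if (length(rows) > 0) {
      problems[[length(problems) + 1L]] <<- data.frame(
        row = rows, field = field, issue = issue, stringsAsFactors = FALSE)
    }
  }
  bad_na <- function(x) is.na(x) | (is.character(x) & !nzchar(trimws(as.character(x))))
  for (f in required_scalar_fields()) {
    note(which(bad_na(cohort[[f]])), f, "missing")
  }
  note(which(!is.na(cohort$sex) & !(cohort$sex %in% sex_levels())), "sex", "invalid level")
  note(which(!is.na(cohort$admission_route) &
               !(cohort$admission_route %in% admission_levels())),
       "admission_route", "invalid level")
  note(which(!is.na(cohort$discharge_mode) &
               !(cohort$discharge_mode %in% discharge_levels())),
       "discharge_mode", "invalid level")
  note(which(!is.na(cohort$age) & cohort$age < 0), "age", "negative")
  note(which(!is.na(cohort$los) & cohort$los < 1), "los", "below 1 day")
  note(which(!is.na(cohort$total_cost) & cohort$total_cost <= 0),
       "total_cost", "nonpositive")
  for (cc in cost_columns()) {
    note(which(!is.na(cohort[[cc]]) & cohort[[cc]] < 0), cc, "negative")
  }
  comp_sum <- rowSums(as.matrix(cohort[cost_columns()]))
  off <- which(!is.na(comp_sum) & !is.na(cohort$total_cost) &
                 abs(comp_sum - cohort$total_cost) > component_tol)
  note(off, "cost_components", "sum differs from total_cost")
  if (length(problems) == 0) {
    return(data.frame(row = integer(0), field = character(0),
                      issue = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, problems)
  out[order(out$row, out$field), , drop = FALSE]
}

#' Read discharge-abstract records from a delimited file
#'
#' Reads a comma-delimited UTF-8 file with header, optionally remapping column
#' names, coerces fields to their contract types and validates every row.
#' Malformed rows are kept and reported through the `"problems"` attribute so
#' that downstream cleaning can count them under the missing-fields criterion
#' rather than dropping them silently.
#'
#' @param path File path.
#' @param schema Optional named character vector mapping contract field name ->
#'   column name in the file.
#' @param component_tol Passed to [validate_cohort()].
#' @return Cohort data frame with attribute `"problems"` (see
#'   [validate_cohort()]).
#' @export
read_records <- function(path, schema = NULL, component_tol = 0.05) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (!is.null(schema)) {
    miss <- setdiff(unname(schema), names(raw))
    if (length(miss) > 0) {
      stop_input("schema maps to column(s) absent from the file: ",
                 paste(miss, collapse = ", "))
    }
    for (i in seq_along(schema)) {
      names(raw)[names(raw) == schema[[i]]] <- names(schema)[i]
    }
  }
  need <- c(required_scalar_fields(), "secondary_dx", "procedures")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop_input("input file is missing required column(s): ",
               paste(miss, collapse = ", "))
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  int <- function(x) suppressWarnings(as.integer(as.numeric(x)))
  lgl <- function(x) {
    lx <- tolower(trimws(x))
    out <- rep(NA, length(x))
    out[lx %in% c("true", "t", "1", "yes", "y")] <- TRUE
    out[lx %in% c("false", "f", "0", "no", "n")] <- FALSE
    out
  }
  cohort <- data.frame(
    record_id = raw$record_id,
    sex = trimws(raw$sex),
    age = int(raw$age),
    allergy = lgl(raw$allergy),
    social_insurance = lgl(raw$social_insurance),
    admission_route = trimws(raw$admission_route),
    discharge_mode = trimws(raw$discharge_mode),
    admission_year = int(raw$admission_year),
    los = int(raw$los),
    primary_dx = trimws(raw$primary_dx),
    secondary_dx = trimws(raw$secondary_dx),
    procedures = trimws(raw$procedures),
    total_cost = num(raw$total_cost),
    stringsAsFactors = FALSE
  )
  for (cc in cost_columns()) cohort[[cc]] <- num(raw[[cc]])
  attr(cohort, "problems") <- validate_cohort(cohort, component_tol)
  cohort
}

#' Write a cohort to a delimited file
#'
#' Currency columns are written with exactly two decimals so a read/write round
#' trip preserves amounts to the printed cent.
#'
#' @param cohort Cohort data frame.
#' @param path Output file path.
#' @export
write_records <- function(cohort, path) {
  out <- cohort
  for (cc in c("total_cost", cost_columns())) {
    out[[cc]] <- sprintf("%.2f", out[[cc]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Construct an MCC/CC code table
#'
#' @param mcc_codes Character vector: secondary-diagnosis codes conferring a
#'   major comorbidity or complication.
#' @param cc_codes Character vector: codes conferring an ordinary comorbidity
#'   or complication. Must be disjoint from `mcc_codes`.
#' @param exclusion Named list: secondary code -> character vector of primary
#'   diagnosis codes that void that secondary code.
#' @return Object of class `cc_table`.
#' @export
cc_table <- function(mcc_codes, cc_codes, exclusion = list()) {
  mcc_codes <- unique(as.character(mcc_codes))
  cc_codes <- unique(as.character(cc_codes))
  if (length(intersect(mcc_codes, cc_codes)) > 0) {
    stop_input("MCC and CC code sets must be disjoint")
  }
  structure(list(mcc_codes = mcc_codes, cc_codes = cc_codes,
                 exclusion = exclusion),
            class = "cc_table")
}

#' Read MCC/CC inclusion and exclusion tables from delimited files
#'
#' @param codes_path Two-column csv (`code`, `level`) with level in
#'   \{MCC, CC\}.
#' @param exclusions_path Two-column csv (`secondary_code`,
#'   `excluded_primary_code`); may list a secondary code several times.
#' @return A [cc_table()].
#' @export
read_cc_tables <- function(codes_path, exclusions_path = NULL) {
  codes <- utils::read.csv(codes_path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("code", "level") %in% names(codes))) {
    stop_input("codes file must have columns 'code' and 'level'")
  }
  bad <- setdiff(unique(codes$level), c("MCC", "CC"))
  if (length(bad) > 0) stop_input("unknown CC level(s): ", paste(bad, collapse = ", "))
  excl <- list()
  if (!is.null(exclusions_path) && file.exists(exclusions_path)) {
    ex <- utils::read.csv(exclusions_path, stringsAsFactors = FALSE,
                          colClasses = "character")
    if (nrow(ex) > 0) {
      excl <- split(ex$excluded_primary_code, ex$secondary_code)
      excl <- lapply(excl, unique)
    }
  }
  cc_table(codes$code[codes$level == "MCC"], codes$code[codes$level == "CC"], excl)
}

#' Write MCC/CC tables in the format [read_cc_tables()] reads
#'
#' @param table A [cc_table()].
#' @param codes_path,exclusions_path Output paths.
#' @export
write_cc_tables <- function(table, codes_path, exclusions_path) {
  codes <- data.frame(
    code = c(table$mcc_codes, table$cc_codes),
    level = c(rep("MCC", length(table$mcc_codes)),
              rep("CC", length(table$cc_codes))),
    stringsAsFactors = FALSE)
  utils::write.csv(codes, codes_path, row.names = FALSE, quote = TRUE)
  if (length(table$exclusion) > 0) {
    ex <- data.frame(
      secondary_code = rep(names(table$exclusion),
                           lengths(table$exclusion)),
      excluded_primary_code = unlist(table$exclusion, use.names = FALSE),
      stringsAsFactors = FALSE)
  } else {
    ex <- data.frame(secondary_code = character(0),
                     excluded_primary_code = character(0))
  }
  utils::write.csv(ex, exclusions_path, row.names = FALSE, quote = TRUE)
  invisible(c(codes_path, exclusions_path))
}

# Severity of one admission given its parsed secondary codes.
cc_level_one <- function(primary, secondary, table) {
  qualifies <- function(incl) {
    hits <- intersect(secondary, incl)
    for (cd in hits) {
      voided <- primary %in% (table$exclusion[[cd]] %||% character(0))
      if (!voided) return(TRUE)
    }
    FALSE
  }
  if (qualifies(table$mcc_codes)) return("MCC")
  if (qualifies(table$cc_codes)) return("CC")
  "NonCC"
}

#' Assign comorbidity/complication severity (MCC / CC / NonCC)
#'
#' An admission has MCC (or CC) when any secondary diagnosis is on the MCC
#' (or CC) inclusion table and the primary diagnosis is not on that code's
#' exclusion list; MCC takes precedence over CC, and admissions qualifying for
#' neither are NonCC.
#'
#' @param cohort Cohort data frame.
#' @param table A [cc_table()].
#' @return Factor with levels NonCC, CC, MCC (one per row of `cohort`).
#' @export
assign_cc_level <- function(cohort, table) {
  secs <- split_codes(cohort$secondary_dx)
  out <- vapply(seq_len(nrow(cohort)), function(i) {
    cc_level_one(cohort$primary_dx[i], secs[[i]], table)
  }, character(1))
  factor(out, levels = cc_levels())
}

#' Apply the cohort exclusion criteria
#'
#' Applies, in order: (1) records with blank or invalid required fields;
#' (2) primary diagnosis or any procedure code outside the grouping scheme;
#' (3) length of stay above `los_max` days; (4) total cost strictly below the
#' low or strictly above the high percentile, with percentiles computed on the
#' cohort surviving the first three criteria. A record violating several
#' criteria is counted only under the first.
#'
#' @param cohort Cohort data frame.
#' @param scheme_codes Character vector of admissible primary-diagnosis and
#'   procedure codes.
#' @param los_max Maximum admissible length of stay in days (default 60).
#' @param trim Length-2 numeric: low and high trimming percentiles
#'   (default `c(1, 99)`).
#' @param component_tol Passed to [validate_cohort()].
#' @param quantile_type Quantile convention for the trim bounds; default 7
#'   (linear interpolation).
#' @return List with `cohort` (retained records) and `log`, an object of class
#'   `drg_exclusion_log` holding per-criterion counts that add up to the input
#'   size.
#' @export
apply_exclusions <- function(cohort, scheme_codes, los_max = 60,
                             trim = c(1, 99), component_tol = 0.05,
                             quantile_type = 7) {
  stopifnot(length(trim) == 2, trim[1] >= 0, trim[1] < trim[2], trim[2] <= 100)
  input_n <- nrow(cohort)
  probs <- attr(cohort, "problems") %||% validate_cohort(cohort, component_tol)
  missing_rows <- unique(probs$row)
  alive <- setdiff(seq_len(input_n), missing_rows)

  procs <- split_codes(cohort$procedures)
  in_scheme <- function(i) {
    cohort$primary_dx[i] %in% scheme_codes &&
      all(procs[[i]] %in% scheme_codes)
  }
  scheme_bad <- alive[!vapply(alive, in_scheme, logical(1))]
  alive <- setdiff(alive, scheme_bad)

  los_bad <- alive[cohort$los[alive] > los_max]
  alive <- setdiff(alive, los_bad)

  if (length(alive) == 0) {
    stop_input("no records survive criteria 1-3; cannot compute trim bounds")
  }
  costs <- cohort$total_cost[alive]
  q <- stats::quantile(costs, probs = trim / 100, type = quantile_type,
                       names = FALSE)
  trim_bad <- alive[costs < q[1] | costs > q[2]]
  alive <- setdiff(alive, trim_bad)

  log <- structure(list(
    input_n = input_n,
    counts = c(missing_fields = length(missing_rows),
               code_not_in_scheme = length(scheme_bad),
               los_gt_max = length(los_bad),
               cost_percentile_trim = length(trim_bad)),
    trim_bounds = q,
    retained_n = length(alive)
  ), class = "drg_exclusion_log")

  retained <- cohort[alive, , drop = FALSE]
  rownames(retained) <- NULL
  attr(retained, "problems") <- NULL
  list(cohort = retained, log = log)
}

#' @export
print.drg_exclusion_log <- function(x, ...) {
  cat("Exclusion log:", x$input_n, "records in,", x$retained_n, "retained\n")
  for (nm in names(x$counts)) {
    cat(sprintf("  %-22s %d\n", nm, x$counts[[nm]]))
  }
  cat(sprintf("  trim bounds: [%.2f, %.2f]\n", x$trim_bounds[1], x$trim_bounds[2]))
  invisible(x)
}

#' Derive analysis features: age band, long stay, severity level
#'
#' Age bands are 0-17, 18-65 and >65 years (band upper bounds inclusive);
#' `long_stay` flags stays above 30 days; `cc_level` comes from
#' [assign_cc_level()].
#'
#' @param cohort Cohort data frame.
#' @param table A [cc_table()].
#' @param long_stay_threshold Days; stays strictly above it are long
#'   (default 30).
#' @return The cohort with columns `age_band` (factor), `long_stay` (logical)
#'   and `cc_level` (factor) appended.
#' @export
derive_features <- function(cohort, table, long_stay_threshold = 30) {
  cohort$age_band <- cut(cohort$age, breaks = c(-Inf, 17, 65, Inf),
                         labels = age_band_levels(), right = TRUE)
  cohort$long_stay <- cohort$los > long_stay_threshold
  cohort$cc_level <- assign_cc_level(cohort, table)
  cohort
}
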