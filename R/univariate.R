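# Rank-based univariate screening of hospitalisation cost.
#
# Costs are heavily right-skewed, so two-level factors are compared with the
# Mann-Whitney U test (normal approximation with tie-corrected variance) and
# multi-level factors with the Kruskal-Wallis H test. Rank means are reported
# per level, matching the descriptive layout of the univariate table.

new_rank_test <- function(variable, levels, n, rank_mean, kind, statistic,
                          p_value) {
  structure(list(variable = variable, levels = levels, n = n,
                 share = 100 * n / sum(n), rank_mean = rank_mean,
                 kind = kind, statistic = statistic, p_value = p_value),
            class = "drg_rank_test")
}

#' @export
print.drg_rank_test <- function(x, ...) {
  cat(sprintf("%s: %s = %.3f, p = %.4g\n", x$variable %||% "rank test",
              x$kind, x$statistic, x$p_value))
  for (i in seq_along(x$levels)) {
    cat(sprintf("  %-20s n = %5d (%5.2f%%)  rank mean = %.2f\n",
                x$levels[i], x$n[i], x$share[i], x$rank_mean[i]))
  }
  invisible(x)
}

#' Mann-Whitney U test for costs in two groups
#'
#' Midranks are used for ties; the Z statistic uses the normal approximation
#' with the tie-corrected variance, and the p-value is two-sided. The sign of
#' Z follows the first group's rank sum (below its null expectation gives a
#' negative Z).
#'
#' @param costs_a,costs_b Numeric vectors, both nonempty.
#' @param labels Length-2 character: group labels for reporting.
#' @param continuity Apply a 0.5 continuity correction (default `FALSE`,
#'   matching conventional asymptotic output for large cost samples).
#' @param variable Optional variable name for reporting.
#' @return A `drg_rank_test` with kind `"Z"`.
#' @export
mann_whitney <- function(costs_a, costs_b, labels = c("a", "b"),
                         continuity = FALSE, variable = NULL) {
  if (length(costs_a) == 0 || length(costs_b) == 0) {
    stop_input("both groups must be nonempty")
  }
  n1 <- length(costs_a)
  n2 <- length(costs_b)
  N <- n1 + n2
  r <- rank(c(costs_a, costs_b))
  r1 <- sum(r[seq_len(n1)])
  u1 <- r1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  v <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (v <= 0) {
    z <- 0
    p <- 1
  } else {
    d <- u1 - mu
    if (continuity) d <- sign(d) * max(0, abs(d) - 0.5)
    z <- d / sqrt(v)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  new_rank_test(variable, labels, c(n1, n2),
                c(mean(r[seq_len(n1)]), mean(r[n1 + seq_len(n2)])),
                "Z", z, p)
}

#' Kruskal-Wallis H test for costs in two or more groups
#'
#' Tie-corrected H with a chi-square reference on k - 1 degrees of freedom,
#' computed via [stats::kruskal.test()]; per-group rank means are attached
#' for reporting.
#'
#' @param groups Named list of at least two nonempty numeric vectors.
#' @param variable Optional variable name for reporting.
#' @return A `drg_rank_test` with kind `"H"`.
#' @export
kruskal_wallis <- function(groups, variable = NULL) {
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2) {
    stop_input("need at least two nonempty groups")
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  r <- rank(values)
  rank_means <- tapply(r, g, mean)
  if (stats::var(values) == 0) {
    h <- 0
    p <- 1
  } else {
    kt <- stats::kruskal.test(values, g)
    h <- unname(kt$statistic)
    p <- kt$p.value
  }
  labs <- names(groups) %||% paste0("g", seq_along(groups))
  new_rank_test(variable, labs, unname(lengths(groups)),
                as.numeric(rank_means), "H", h, p)
}

#' Screen candidate factors against cost with rank tests
#'
#' Two-level factors are tested with [mann_whitney()], multi-level factors
#' with [kruskal_wallis()]. Logical columns are treated as no/yes factors.
#'
#' @param cohort Cohort data frame with derived features.
#' @param variables Character vector of column names to screen.
#' @param alpha Significance level for the flag (default 0.05).
#' @param cost_column Response column (default `"total_cost"`).
#' @return Object of class `drg_screen`: a list with `results` (one
#'   `drg_rank_test` per variable) and `table`, a tidy data frame with one
#'   row per factor level and the test statistic, p-value and significance
#'   flag on each factor's first row.
#' @export
screen_factors <- function(cohort,
                           variables = c("sex", "age_band", "allergy",
                                         "social_insurance", "admission_route",
                                         "cc_level", "discharge_mode",
                                         "long_stay"),
                           alpha = 0.05, cost_column = "total_cost") {
  missing_vars <- setdiff(c(variables, cost_column), names(cohort))
  if (length(missing_vars) > 0) {
    stop_input("variable(s) absent from cohort: ",
               paste(missing_vars, collapse = ", "))
  }
  results <- list()
  rows <- list()
  for (v in variables) {
    x <- cohort[[v]]
    if (is.logical(x)) x <- factor(ifelse(x, "yes", "no"), levels = c("no", "yes"))
    if (!is.factor(x)) x <- factor(x)
    x <- droplevels(x)
    if (nlevels(x) < 2) {
      stop_input("variable '", v, "' has fewer than two observed levels")
    }
    grp <- split(cohort[[cost_column]], x)
    res <- if (nlevels(x) == 2) {
      mann_whitney(grp[[1]], grp[[2]], labels = levels(x), variable = v)
    } else {
      kruskal_wallis(grp, variable = v)
    }
    results[[v]] <- res
    k <- length(res$levels)
    rows[[v]] <- data.frame(
      variable = c(v, rep("", k - 1)),
      level = res$levels,
      n = res$n,
      share_pct = round(res$share, 2),
      rank_mean = round(res$rank_mean, 2),
      statistic_kind = c(res$kind, rep("", k - 1)),
      statistic = c(round(res$statistic, 3), rep(NA, k - 1)),
      p_value = c(res$p_value, rep(NA, k - 1)),
      significant = c(res$p_value < alpha, rep(NA, k - 1)),
      stringsAsFactors = FALSE)
  }
  structure(list(results = results,
                 table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 alpha = alpha),
            class = "drg_screen")
}

#' @export
print.drg_screen <- function(x, ...) {
  cat("Univariate rank-test screen (alpha =", x$alpha, ")\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Write the univariate screening report
#'
#' @param screen A [screen_factors()] result.
#' @param path Output path (tab-delimited).
#' @export
write_univariate_report <- function(screen, path) {
  utils::write.table(screen$table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}
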