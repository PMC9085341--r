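# Group homogeneity validation and payment standards.
#
# A candidate ADRG is worth subdividing when its cost CV exceeds 1; after
# grouping, a group is acceptably homogeneous when its CV is at most 1, and
# between-group separation is checked with the Kruskal-Wallis test. Each
# group's payment standard is its median cost, and its upper limit is the
# boxplot fence P75 + 1.5 * IQR; admissions costing strictly more are excess
# cases.

#' Coefficient of variation of costs
#'
#' Sample (n - 1) standard deviation divided by the mean.
#'
#' @param costs Numeric vector with at least two values and positive mean.
#' @return Dimensionless ratio.
#' @export
coefficient_of_variation <- function(costs) {
  if (length(costs) < 2) stop_input("need at least two values")
  m <- mean(costs)
  if (m <= 0) stop_input("mean must be positive")
  stats::sd(costs) / m
}

#' Subdivision premise check for a candidate group
#'
#' Recommends subdividing exactly when the cost CV strictly exceeds 1.
#'
#' @param costs Numeric cost vector (or a cohort data frame with a
#'   `total_cost` column).
#' @return List with `cv` and logical `subdivide`.
#' @export
premise_check <- function(costs) {
  if (is.data.frame(costs)) costs <- costs$total_cost
  cv <- coefficient_of_variation(costs)
  structure(list(cv = cv, subdivide = cv > 1), class = "drg_premise")
}

#' @export
print.drg_premise <- function(x, ...) {
  cat(sprintf("cost CV = %.3f -> %s\n", x$cv,
              if (x$subdivide) "subdivide (CV > 1)" else "do not subdivide (CV <= 1)"))
  invisible(x)
}

#' Payment upper limit from the boxplot fence
#'
#' @param p75 75th percentile of group cost.
#' @param iqr Interquartile range of group cost.
#' @return `p75 + 1.5 * iqr`, rounded to the cent.
#' @export
payment_fence <- function(p75, iqr) {
  round_currency(p75 + 1.5 * iqr)
}

#' Payment-standard summary for one cost group
#'
#' The standard cost is the group median; the upper limit is the fence
#' P75 + 1.5 * IQR; excess cases cost strictly more than the upper limit.
#' Currency is reported at two decimals (half-to-even).
#'
#' @param costs Nonempty numeric cost vector.
#' @param quantile_type Quantile convention (default 7, linear
#'   interpolation; 6 approximates the inclusive convention of common
#'   commercial packages).
#' @return List: `n`, `median`, `p25`, `p75`, `iqr`, `upper_limit`,
#'   `excess_n`, `excess_rate` (percent).
#' @export
payment_standard <- function(costs, quantile_type = 7) {
  if (length(costs) == 0) stop_input("empty group")
  q <- stats::quantile(costs, c(0.25, 0.5, 0.75), type = quantile_type,
                       names = FALSE)
  p25 <- round_currency(q[1])
  p75 <- round_currency(q[3])
  iqr <- round_currency(p75 - p25)
  upper <- payment_fence(p75, iqr)
  excess_n <- sum(costs > upper)
  list(n = length(costs), median = round_currency(q[2]), p25 = p25,
       p75 = p75, iqr = iqr, upper_limit = upper, excess_n = excess_n,
       excess_rate = 100 * excess_n / length(costs))
}

#' Per-group payment standards for a grouped cohort
#'
#' @param cohort Cohort data frame.
#' @param groups Integer/character vector of group labels, one per record.
#' @param descriptions Optional named descriptions per group label.
#' @param quantile_type Passed to [payment_standard()].
#' @return Data frame, one row per group: n, CV, standard (median) cost,
#'   P25, P75, IQR, upper limit, excess count and rate.
#' @export
group_payments <- function(cohort, groups, descriptions = NULL,
                           quantile_type = 7) {
  split_costs <- split(cohort$total_cost, groups)
  rows <- lapply(names(split_costs), function(gname) {
    cs <- split_costs[[gname]]
    ps <- payment_standard(cs, quantile_type)
    data.frame(
      group = gname,
      description = descriptions[[gname]] %||% "",
      n = ps$n,
      cv = if (length(cs) >= 2) round(coefficient_of_variation(cs), 2) else NA_real_,
      median = ps$median, p25 = ps$p25, p75 = ps$p75, iqr = ps$iqr,
      upper_limit = ps$upper_limit, excess_n = ps$excess_n,
      excess_rate = round(ps$excess_rate, 2),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Validate a grouping by homogeneity and separation
#'
#' Computes each group's cost CV (undefined and flagged for singleton
#' groups), counts groups meeting the CV <= 1 homogeneity rule, and tests
#' between-group separation with the Kruskal-Wallis test.
#'
#' @param cohort Cohort data frame.
#' @param groups Group label per record (at least two distinct groups).
#' @param alpha Significance level for the separation verdict (default
#'   0.05).
#' @return Object of class `drg_validation`: per-group `cv` table,
#'   `n_homogeneous` (CV <= 1), `kw` (a `drg_rank_test`), and the verdicts.
#' @export
validate_grouping <- function(cohort, groups, alpha = 0.05) {
  split_costs <- split(cohort$total_cost, groups)
  if (length(split_costs) < 2) {
    stop_input("need at least two groups to validate")
  }
  cv_tab <- data.frame(
    group = names(split_costs),
    n = unname(lengths(split_costs)),
    cv = vapply(split_costs, function(cs) {
      if (length(cs) < 2) NA_real_ else coefficient_of_variation(cs)
    }, numeric(1)),
    stringsAsFactors = FALSE)
  cv_tab$singleton <- cv_tab$n < 2
  kw <- kruskal_wallis(split_costs, variable = "cost group")
  structure(list(
    cv_table = cv_tab,
    n_homogeneous = sum(cv_tab$cv <= 1, na.rm = TRUE),
    n_groups = nrow(cv_tab),
    kw = kw,
    separated = kw$p_value < alpha,
    alpha = alpha
  ), class = "drg_validation")
}

#' @export
print.drg_validation <- function(x, ...) {
  cat(sprintf("%d of %d groups have CV <= 1; Kruskal-Wallis H = %.2f, p = %.3g (%s)\n",
              x$n_homogeneous, x$n_groups, x$kw$statistic, x$kw$p_value,
              if (x$separated) "groups differ" else "no separation"))
  invisible(x)
}

#' Write the grouping/payment report
#'
#' @param payments A [group_payments()] result.
#' @param path Output path (tab-delimited).
#' @export
write_payment_report <- function(payments, path) {
  out <- payments
  for (cc in c("median", "p25", "p75", "iqr", "upper_limit")) {
    out[[cc]] <- sprintf("%.2f", out[[cc]])
  }
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
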