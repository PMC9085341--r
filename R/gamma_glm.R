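# Multivariable gamma regression of total cost with log link.
#
# The gamma GLM handles right-skewed positive cost data on the original
# scale: exponentiated coefficients are cost ratios (CR), the multiplicative
# effect of a factor level relative to its reference. Marginal means average
# response-scale predictions over a balanced grid of the other factors, so
# for a log link the ratio of a level's marginal mean to its reference's
# equals that level's CR exactly.

#' Model specification for the cost regression
#'
#' Declares the factor set and reference levels: sex (ref female), age band
#' (ref 0-17), social insurance (ref yes), admission route (ref
#' outpatient/other), comorbidity level (ref NonCC), long stay (ref no) and
#' discharge mode (ref home). The first level of each vector is the
#' reference.
#'
#' @param include Optional character vector restricting the factor set (in
#'   the given order).
#' @return Object of class `drg_model_spec`.
#' @export
model_spec <- function(include = NULL) {
  factors <- list(
    sex = sex_levels(),
    age_band = age_band_levels(),
    social_insurance = c("yes", "no"),
    admission_route = admission_levels(),
    cc_level = cc_levels(),
    long_stay = c("no", "yes"),
    discharge_mode = discharge_levels()
  )
  if (!is.null(include)) {
    unknown <- setdiff(include, names(factors))
    if (length(unknown) > 0) {
      stop_input("unknown factor(s): ", paste(unknown, collapse = ", "))
    }
    factors <- factors[include]
  }
  structure(list(response = "total_cost", factors = factors),
            class = "drg_model_spec")
}

# Model frame with every factor releveled so its declared reference is first.
build_model_frame <- function(cohort, spec) {
  mf <- data.frame(row.names = seq_len(nrow(cohort)))
  mf[[spec$response]] <- cohort[[spec$response]]
  for (f in names(spec$factors)) {
    if (!(f %in% names(cohort))) {
      stop_input("factor '", f, "' absent from cohort")
    }
    x <- cohort[[f]]
    if (is.logical(x)) x <- ifelse(x, "yes", "no")
    x <- factor(as.character(x), levels = spec$factors[[f]])
    if (anyNA(x)) {
      stop_input("factor '", f, "' has values outside its declared levels")
    }
    mf[[f]] <- x
  }
  mf
}

#' Fit the log-link gamma regression of cost
#'
#' Fits by iteratively reweighted least squares (via [stats::glm()]) until
#' the relative deviance change falls below `tol`; the dispersion is the
#' Pearson chi-square estimate, and confidence intervals are Wald intervals
#' on the log scale, exponentiated to cost-ratio scale.
#'
#' @param cohort Cleaned cohort with derived features and positive costs.
#' @param spec A [model_spec()].
#' @param tol IRLS convergence tolerance on the relative deviance change
#'   (default 1e-8).
#' @param max_iter Maximum IRLS iterations (default 100).
#' @param conf_level Confidence level for the Wald intervals (default 0.95).
#' @return Object of class `drg_gamma_fit`: the underlying `glm`, the
#'   coefficient table, the cost-ratio table (`cr_table`), the Pearson
#'   dispersion, and convergence diagnostics.
#' @export
fit_gamma <- function(cohort, spec = model_spec(), tol = 1e-8,
                      max_iter = 100, conf_level = 0.95) {
  if (any(cohort[[spec$response]] <= 0)) {
    stop_input("all costs must be strictly positive")
  }
  mf <- build_model_frame(cohort, spec)
  for (f in names(spec$factors)) {
    obs <- unique(as.character(mf[[f]]))
    if (!(spec$factors[[f]][1] %in% obs)) {
      stop_input("reference level of '", f, "' is not observed in the data")
    }
    if (length(obs) < 2) {
      stop_input("factor '", f, "' is constant in this cohort (degenerate column)")
    }
  }
  fml <- stats::as.formula(paste(spec$response, "~",
                                 paste(names(spec$factors), collapse = " + ")))
  fit <- stats::glm(fml, data = mf, family = stats::Gamma(link = "log"),
                    control = stats::glm.control(epsilon = tol, maxit = max_iter))
  if (!fit$converged) {
    stop("gamma IRLS did not converge in ", max_iter,
         " iterations (deviance trace: final ", format(fit$deviance), ")",
         call. = FALSE)
  }
  sm <- summary(fit)  # dispersion = Pearson chi-square / residual df for Gamma
  coefs <- sm$coefficients
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)

  rows <- list()
  for (f in names(spec$factors)) {
    levs <- levels(mf[[f]])
    for (lv in levs) {
      if (lv == levs[1]) {
        rows[[paste(f, lv)]] <- data.frame(
          variable = f, level = lv, is_ref = TRUE, estimate = 0, se = NA_real_,
          cr = 1, cr_lo = NA_real_, cr_hi = NA_real_, p_value = NA_real_,
          stringsAsFactors = FALSE)
      } else {
        cn <- paste0(f, lv)
        b <- coefs[cn, "Estimate"]
        se <- coefs[cn, "Std. Error"]
        rows[[paste(f, lv)]] <- data.frame(
          variable = f, level = lv, is_ref = FALSE, estimate = b, se = se,
          cr = exp(b), cr_lo = exp(b - zq * se), cr_hi = exp(b + zq * se),
          p_value = 2 * stats::pnorm(-abs(b / se)),
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(
    glm = fit,
    spec = spec,
    coefficients = coefs,
    dispersion = sm$dispersion,
    cr_table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
    conf_level = conf_level,
    converged = fit$converged,
    iterations = fit$iter
  ), class = "drg_gamma_fit")
}

#' @export
print.drg_gamma_fit <- function(x, ...) {
  cat("Gamma GLM (log link),", length(x$glm$y), "records, dispersion",
      format(x$dispersion, digits = 4), "\n")
  tb <- x$cr_table
  tb$estimate <- round(tb$estimate, 4)
  tb[c("cr", "cr_lo", "cr_hi")] <- round(tb[c("cr", "cr_lo", "cr_hi")], 3)
  print(tb[c("variable", "level", "cr", "cr_lo", "cr_hi", "p_value")],
        row.names = FALSE)
  invisible(x)
}

#' Marginal means over a balanced factor grid
#'
#' For each level of each factor, the response-scale prediction is averaged
#' over an equal-weight grid of all other factors' levels. With a log link
#' and main effects only, the ratio of a level's marginal mean to its
#' reference level's marginal mean equals that level's cost ratio.
#'
#' @param fit A [fit_gamma()] result.
#' @return Data frame with one row per factor level: `marginal_mean`
#'   (currency) and `difference` from the factor's reference level.
#' @export
marginal_means <- function(fit) {
  if (!inherits(fit, "drg_gamma_fit")) stop_input("fit must come from fit_gamma()")
  spec <- fit$spec
  grid <- expand.grid(lapply(spec$factors, function(lv) factor(lv, levels = lv)),
                      KEEP.OUT.ATTRS = FALSE)
  pred <- stats::predict(fit$glm, newdata = grid, type = "response")
  rows <- list()
  for (f in names(spec$factors)) {
    levs <- spec$factors[[f]]
    mm <- vapply(levs, function(lv) mean(pred[grid[[f]] == lv]), numeric(1))
    rows[[f]] <- data.frame(
      variable = f, level = levs, is_ref = levs == levs[1],
      marginal_mean = unname(mm),
      difference = unname(mm - mm[1]),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Write the multivariable regression report
#'
#' One row per factor level: marginal mean, difference from reference, cost
#' ratio with confidence interval and p-value.
#'
#' @param fit A [fit_gamma()] result.
#' @param path Output path (tab-delimited).
#' @export
write_gamma_report <- function(fit, path) {
  mm <- marginal_means(fit)
  tb <- merge(fit$cr_table, mm[c("variable", "level", "marginal_mean", "difference")],
              by = c("variable", "level"), sort = FALSE)
  tb <- tb[order(match(tb$variable, names(fit$spec$factors)),
                 match(tb$level, unlist(fit$spec$factors))), ]
  out <- data.frame(
    variable = tb$variable,
    level = ifelse(tb$is_ref, paste0("Ref: ", tb$level), tb$level),
    marginal_mean = sprintf("%.2f", tb$marginal_mean),
    difference = ifelse(tb$is_ref, "", sprintf("%.2f", tb$difference)),
    cost_ratio = ifelse(tb$is_ref, "1", sprintf("%.2f", tb$cr)),
    ci_low = ifelse(tb$is_ref, "", sprintf("%.2f", tb$cr_lo)),
    ci_high = ifelse(tb$is_ref, "", sprintf("%.2f", tb$cr_hi)),
    p_value = ifelse(tb$is_ref, "", format(tb$p_value, digits = 3)),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
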