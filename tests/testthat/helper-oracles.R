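# Independent oracles and small fixture builders shared across tests.

# A tiny hand-built cohort with fully controlled fields.
make_cohort <- function(n = 10, cost = NULL, seed = 99) {
  set.seed(seed)
  cost <- cost %||% round(rgamma(n, 2, 1 / 5000), 2)
  shares <- c(0.4, 0.25, 0.15, 0.05, 0.05, 0.04, 0.01, 0.05)
  comps <- round(outer(cost, shares), 2)
  comps[, 1] <- round(comps[, 1] + (cost - rowSums(comps)), 2)
  df <- data.frame(
    record_id = sprintf("T%03d", seq_len(n)),
    sex = rep(c("male", "female"), length.out = n),
    age = sample(1:95, n, replace = TRUE),
    allergy = rep(c(TRUE, FALSE), length.out = n),
    social_insurance = rep(c(FALSE, TRUE), length.out = n),
    admission_route = rep(c("emergency", "outpatient_other"), length.out = n),
    discharge_mode = rep("home", n),
    admission_year = rep(2019L, n),
    los = sample(1:20, n, replace = TRUE),
    primary_dx = rep("D001", n),
    secondary_dx = rep("", n),
    procedures = rep("", n),
    total_cost = cost,
    stringsAsFactors = FALSE
  )
  comp_df <- as.data.frame(comps)
  names(comp_df) <- paste0("cost_", cost_categories())
  cbind(df, comp_df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exact two-sided Mann-Whitney p by enumeration of all group assignments.
exact_mw_p <- function(a, b) {
  n1 <- length(a)
  N <- n1 + length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(b) / 2
  obs_dev <- abs(u_of(seq_len(n1)) - mu)
  combs <- combn(N, n1)
  devs <- apply(combs, 2, function(idx) abs(u_of(idx) - mu))
  mean(devs >= obs_dev - 1e-9)
}

# All set partitions of a character vector of categories.
all_set_partitions <- function(items) {
  if (length(items) == 1) return(list(list(items)))
  first <- items[1]
  rest <- all_set_partitions(items[-1])
  out <- list()
  for (p in rest) {
    for (j in seq_along(p)) {
      q <- p
      q[[j]] <- c(first, q[[j]])
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(list(first), p)
  }
  out
}

oracle_anova_p <- function(values, g) {
  if (length(unique(g)) < 2) return(1)
  tb <- summary(stats::aov(values ~ factor(g)))[[1]]
  tb[["Pr(>F)"]][1]
}

oracle_assign <- function(cats, partition) {
  g <- integer(length(cats))
  for (j in seq_along(partition)) g[cats %in% partition[[j]]] <- j
  g
}

# Canonical string form of a partition, order-insensitive.
canon_partition <- function(partition) {
  paste(sort(vapply(partition, function(s) paste(sort(s), collapse = "+"),
                    character(1))), collapse = "|")
}

# Brute-force best (minimum ANOVA p) partition with >= 2 groups.
oracle_best_partition <- function(values, cats, scale = "nominal") {
  lev <- if (scale == "ordinal") sort(unique(cats)) else unique(cats)
  parts <- if (scale == "ordinal") {
    out <- list()
    c_cats <- length(lev)
    for (mask in 0:(2^(c_cats - 1) - 1)) {
      cuts <- which(bitwAnd(mask, 2^(seq_len(c_cats - 1) - 1)) > 0)
      bounds <- c(0, cuts, c_cats)
      out[[length(out) + 1L]] <- lapply(seq_len(length(bounds) - 1),
                                        function(j) lev[(bounds[j] + 1):bounds[j + 1]])
    }
    out
  } else {
    all_set_partitions(lev)
  }
  parts <- Filter(function(p) length(p) >= 2, parts)
  ps <- vapply(parts, function(p) oracle_anova_p(values, oracle_assign(cats, p)),
               numeric(1))
  list(partition = parts[[which.min(ps)]], p = min(ps))
}

# Brute-force best binary CART split: minimise total child SSE.
oracle_best_binary_split <- function(data, predictors, target = "total_cost") {
  values <- data[[target]]
  sse <- function(v) sum((v - mean(v))^2)
  best <- NULL
  for (pred in predictors) {
    lev <- unique(as.character(data[[pred]]))
    if (length(lev) < 2) next
    rest <- lev[-1]
    for (mask in 0:(2^(length(rest)) - 1)) {
      left <- c(lev[1], rest[bitwAnd(mask, 2^(seq_along(rest) - 1)) > 0])
      if (length(left) == length(lev)) next
      inl <- as.character(data[[pred]]) %in% left
      if (!any(inl) || all(inl)) next
      tot <- sse(values[inl]) + sse(values[!inl])
      if (is.null(best) || tot < best$sse - 1e-9) {
        best <- list(predictor = pred, left = sort(left), sse = tot)
      }
    }
  }
  best
}

generator_truth <- function() {
  c(sexmale = 1.05, `age_band18-65` = 2.22, `age_band>65` = 2.63,
    social_insuranceno = 1, admission_routeemergency = 1.20,
    cc_levelCC = 1.48, cc_levelMCC = 2.25, long_stayyes = 4.23,
    discharge_modetransfer = 1.76, discharge_modedeath = 1.55,
    discharge_modeother = 1.35)
}

# Parameter-recovery suite: for each of `n_rep` seeded study-sized cohorts,
# does each factor's 95% Wald CI cover the generator's true multiplier?
# Memoised because two test files assert on the same replicates.
recovery_hits <- local({
  cache <- NULL
  function(n_rep = 40) {
    if (!is.null(cache)) return(cache)
    truth <- generator_truth()
    tabs <- study_tables()
    hits <- matrix(NA, n_rep, length(truth), dimnames = list(NULL, names(truth)))
    for (s in seq_len(n_rep)) {
      co <- derive_features(generate_cohort(default_config(), seed = 5000 + s,
                                            tables = tabs), tabs$cc_table)
      fit <- fit_gamma(co)
      tb <- fit$cr_table[!fit$cr_table$is_ref, ]
      key <- paste0(tb$variable, tb$level)
      ord <- match(names(truth), key)
      hits[s, ] <- truth >= tb$cr_lo[ord] & truth <= tb$cr_hi[ord]
    }
    cache <<- hits
    hits
  }
})

# Fixed synthetic study cohort shared by the slower tests.
study_tables <- function() generate_cc_tables(1)
study_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tabs <- study_tables()
      co <- generate_cohort(default_config(), tables = tabs)
      cache <<- derive_features(co, tabs$cc_table)
    }
    cache
  }
})
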