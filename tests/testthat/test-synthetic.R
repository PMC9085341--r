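test_that("default configuration encodes the published prevalences and effects", {
  cfg <- default_config()
  expect_equal(cfg$category_probs$sex[["male"]], 0.6178)
  expect_equal(cfg$category_probs$cc_level[["MCC"]], 0.2243)
  expect_equal(cfg$category_probs$long_stay[["yes"]], 0.0409)
  expect_equal(cfg$effect_multipliers$age_band[[">65"]], 2.63)
  expect_equal(cfg$effect_multipliers$long_stay[["yes"]], 4.23)
  expect_equal(cfg$effect_multipliers$discharge_mode[["transfer"]], 1.76)
  # reference cell: product of reference-level multipliers is 1
  ref_prod <- prod(vapply(cfg$effect_multipliers, function(m) m[[1]], numeric(1)))
  expect_equal(ref_prod, 1)
})

test_that("analytic calibration hits the target mean and CV in expectation", {
  cfg <- default_config()
  # recompute the two moment identities from the config itself
  e1 <- 1; ratio <- 1
  for (f in names(cfg$effect_multipliers)) {
    p <- cfg$category_probs[[f]]; p <- p / sum(p)
    m <- cfg$effect_multipliers[[f]][names(p)]
    e1 <- e1 * sum(p * m)
    ratio <- ratio * sum(p * m^2) / sum(p * m)^2
  }
  expect_equal(cfg$baseline_mean * e1, cfg$target_mean, tolerance = 1e-3)
  implied_cv <- sqrt((1 + 1 / cfg$gamma_shape) * ratio - 1)
  expect_equal(implied_cv, cfg$target_cv, tolerance = 1e-6)
})

test_that("generation is deterministic under a fixed seed", {
  tabs <- generate_cc_tables(3)
  a <- generate_cohort(default_config(n = 300, seed = 3), tables = tabs)
  b <- generate_cohort(default_config(n = 300, seed = 3), tables = tabs)
  attr(a, "expected_cost") <- NULL
  attr(b, "expected_cost") <- NULL
  expect_identical(a, b)
  c <- generate_cohort(default_config(n = 300, seed = 4), tables = tabs)
  expect_false(identical(a$total_cost, c$total_cost))
})

test_that("generated records always satisfy the record invariants", {
  tabs <- generate_cc_tables(13)
  co <- generate_cohort(default_config(n = 2000, seed = 13), tables = tabs)
  expect_equal(nrow(validate_cohort(co)), 0)
  expect_true(all(co$los >= 1 & co$los <= 60))
  expect_true(all(co$total_cost > 0))
  comp_sum <- rowSums(co[paste0("cost_", cost_categories())])
  expect_true(all(abs(comp_sum - co$total_cost) <= 0.05))
  # severity re-derived from the codes matches the drawn mix roughly
  feats <- derive_features(co, tabs$cc_table)
  expect_true(all(levels(feats$cc_level) == c("NonCC", "CC", "MCC")))
})

test_that("empirical prevalences converge to the configured probabilities", {
  tabs <- generate_cc_tables(21)
  co <- generate_cohort(default_config(n = 50000, seed = 21), tables = tabs)
  co <- derive_features(co, tabs$cc_table)
  cfg <- default_config()
  expect_equal(mean(co$sex == "male"), 0.6178, tolerance = 0.01)
  expect_equal(mean(co$admission_route == "emergency"), 0.5482, tolerance = 0.01)
  expect_equal(unname(table(co$cc_level)["MCC"] / nrow(co)),
               cfg$category_probs$cc_level[["MCC"]] /
                 sum(cfg$category_probs$cc_level), tolerance = 0.015)
  expect_equal(mean(co$long_stay), 0.0409, tolerance = 0.005)
  expect_equal(mean(co$age > 65), 0.5505 / sum(cfg$category_probs$age_band),
               tolerance = 0.01)
  # LOS distribution near its targets (truncation shifts moments slightly)
  expect_equal(mean(co$los), 10.70, tolerance = 0.08 * 10.70)
  expect_equal(sd(co$los), 8.61, tolerance = 0.12 * 8.61)
})

test_that("the generator's age effect on cost matches its configured multiplier", {
  tabs <- generate_cc_tables(31)
  co <- generate_cohort(default_config(n = 50000, seed = 31), tables = tabs)
  co <- derive_features(co, tabs$cc_table)
  mu <- attr(co, "expected_cost")
  cfg <- default_config()
  m_age <- cfg$effect_multipliers$age_band[as.character(co$age_band)]
  # cost divided by all non-age effects isolates the age multiplier
  adj <- co$total_cost / (mu / m_age)
  ratio <- mean(adj[co$age_band == ">65"]) / mean(adj[co$age_band == "0-17"])
  expect_equal(ratio, 2.63, tolerance = 0.1 * 2.63)
})

test_that("synthetic CC tables have the promised structure", {
  tabs <- generate_cc_tables(1, n_codes = 3)
  expect_length(tabs$cc_table$mcc_codes, 1)
  expect_length(tabs$cc_table$cc_codes, 1)
  expect_length(tabs$neutral_codes, 1)
  expect_length(tabs$cc_table$exclusion, 0)
  expect_error(generate_cc_tables(1, n_codes = 2), "at least 3")
  # a record built to hit an exclusion pair is voided to NonCC
  tab <- cc_table("S001", "S010", exclusion = list(S001 = "D007"))
  co <- make_cohort(1)
  co$primary_dx <- "D007"
  co$secondary_dx <- "S001"
  expect_equal(as.character(assign_cc_level(co, tab)), "NonCC")
})

test_that("gamma fits on replicated cohorts recover the true multipliers", {
  hits <- recovery_hits()
  # aggregate Wald coverage across all factors is close to nominal
  expect_gte(mean(hits), 0.90)
  # and no single factor's coverage collapses
  expect_true(all(colMeans(hits) >= 0.85),
              info = paste(colMeans(hits), collapse = ","))
})
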