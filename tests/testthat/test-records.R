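test_that("a written cohort reads back field-by-field", {
  tabs <- generate_cc_tables(7)
  co <- generate_cohort(default_config(n = 120, seed = 7), tables = tabs)
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(co, path)
  back <- read_records(path)
  expect_equal(nrow(back), nrow(co))
  expect_equal(nrow(attr(back, "problems")), 0)
  for (f in c("record_id", "sex", "primary_dx", "secondary_dx", "procedures")) {
    expect_identical(back[[f]], co[[f]])
  }
  for (f in c("age", "los", "admission_year")) {
    expect_identical(as.integer(back[[f]]), as.integer(co[[f]]))
  }
  for (f in c("total_cost", paste0("cost_", cost_categories()))) {
    expect_equal(back[[f]], round(co[[f]], 2), tolerance = 1e-9)
  }
})

test_that("malformed rows are flagged, not dropped", {
  co <- make_cohort(5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(co, path)
  lines <- readLines(path)
  # blank out total_cost in data row 3
  row <- read.csv(path, colClasses = "character")[3, ]
  row$total_cost <- ""
  fields <- vapply(as.character(row), function(x) paste0('"', x, '"'), character(1))
  lines[4] <- paste(fields, collapse = ",")
  writeLines(lines, path)
  back <- read_records(path)
  expect_equal(nrow(back), 5)
  probs <- attr(back, "problems")
  expect_true(3 %in% probs$row)
  expect_true(any(probs$field == "total_cost" & probs$row == 3))
  expect_false(any(probs$row %in% c(1, 2, 4, 5)))
})

test_that("reading fails loudly when a required column is absent", {
  co <- make_cohort(3)
  co$total_cost <- NULL
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(co, path, row.names = FALSE)
  expect_error(read_records(path), "total_cost")
})

test_that("MCC/CC assignment follows inclusion and exclusion rules", {
  tab <- cc_table(mcc_codes = c("S001", "S002"), cc_codes = c("S010", "S011"),
                  exclusion = list(S001 = "D009", S010 = "D005"))
  co <- make_cohort(6)
  co$primary_dx <- c("D001", "D001", "D009", "D005", "D001", "D001")
  co$secondary_dx <- c("S001",       # MCC code, primary not excluded -> MCC
                       "",           # no secondary -> NonCC
                       "S001",       # MCC code voided by primary -> NonCC
                       "S010",       # sole CC code voided -> NonCC
                       "S010;S001",  # both qualify -> MCC precedence
                       "S010")       # CC code -> CC
  got <- assign_cc_level(co, tab)
  expect_equal(as.character(got),
               c("MCC", "NonCC", "NonCC", "NonCC", "MCC", "CC"))
})

test_that("MCC/CC assignment is invariant to secondary-code order", {
  tab <- cc_table(c("S001"), c("S010", "S011"), exclusion = list(S010 = "D001"))
  co <- make_cohort(1)
  co$primary_dx <- "D001"
  perms <- list(c("S010", "S011", "S001"), c("S001", "S010", "S011"),
                c("S011", "S001", "S010"))
  levels_seen <- vapply(perms, function(p) {
    co$secondary_dx <- paste(p, collapse = ";")
    as.character(assign_cc_level(co, tab))
  }, character(1))
  expect_true(all(levels_seen == levels_seen[1]))
})

test_that("MCC and CC inclusion sets must be disjoint", {
  expect_error(cc_table(c("S001"), c("S001")), "disjoint")
})

test_that("CC tables round-trip through their file format", {
  tabs <- generate_cc_tables(3, n_codes = 12)
  codes_path <- withr::local_tempfile(fileext = ".csv")
  excl_path <- withr::local_tempfile(fileext = ".csv")
  write_cc_tables(tabs$cc_table, codes_path, excl_path)
  back <- read_cc_tables(codes_path, excl_path)
  expect_setequal(back$mcc_codes, tabs$cc_table$mcc_codes)
  expect_setequal(back$cc_codes, tabs$cc_table$cc_codes)
  expect_setequal(names(back$exclusion), names(tabs$cc_table$exclusion))
  for (cd in names(back$exclusion)) {
    expect_setequal(back$exclusion[[cd]], tabs$cc_table$exclusion[[cd]])
  }
})

test_that("exclusion criteria are applied in order and account for every record", {
  tabs <- generate_cc_tables(11)
  co <- generate_cohort(default_config(n = 100, seed = 11), tables = tabs)
  co$los[7] <- 61L
  res <- apply_exclusions(co, tabs$scheme_codes)
  expect_equal(res$log$counts[["los_gt_max"]], 1)
  expect_equal(res$log$input_n, 100)
  expect_equal(sum(res$log$counts) + res$log$retained_n, 100)
  # a record violating los AND scheme is counted once, under the earlier rule
  co2 <- co
  co2$primary_dx[7] <- "ZZZ"
  res2 <- apply_exclusions(co2, tabs$scheme_codes)
  expect_equal(res2$log$counts[["code_not_in_scheme"]], 1)
  expect_equal(res2$log$counts[["los_gt_max"]], 0)
})

test_that("percentile trimming removes nothing from a constant-cost cohort", {
  co <- make_cohort(50, cost = rep(1000, 50))
  res <- apply_exclusions(co, scheme_codes = "D001")
  expect_equal(res$log$retained_n, 50)
  expect_equal(sum(res$log$counts), 0)
})

test_that("widening the trim percentiles never drops a previously retained record", {
  tabs <- generate_cc_tables(5)
  co <- generate_cohort(default_config(n = 400, seed = 5), tables = tabs)
  narrow <- apply_exclusions(co, tabs$scheme_codes, trim = c(5, 95))
  wide <- apply_exclusions(co, tabs$scheme_codes, trim = c(1, 99))
  expect_true(all(narrow$cohort$record_id %in% wide$cohort$record_id))
})

test_that("an engineered raw cohort reproduces the published cleaning arithmetic", {
  # 6214 admissions; 902 violate criteria 1-3 and the 1/99-percentile trim of
  # the 5312 survivors removes 108 more, leaving the study-sized 5204.
  tabs <- generate_cc_tables(2022)
  co <- generate_cohort(default_config(n = 6214, seed = 2022), tables = tabs)
  co$total_cost[1:350] <- NA_real_
  co$primary_dx[351:700] <- "NOT_IN_SCHEME"
  co$los[701:902] <- 61L
  res <- apply_exclusions(co, tabs$scheme_codes)
  expect_equal(res$log$counts[["missing_fields"]], 350)
  expect_equal(res$log$counts[["code_not_in_scheme"]], 350)
  expect_equal(res$log$counts[["los_gt_max"]], 202)
  expect_equal(res$log$counts[["cost_percentile_trim"]], 108)
  expect_equal(res$log$retained_n, 5204)
})

test_that("derived features respect the band and threshold boundaries", {
  tab <- cc_table("S001", "S010")
  co <- make_cohort(6)
  co$age <- c(0L, 17L, 18L, 65L, 66L, 99L)
  co$los <- c(30L, 31L, 1L, 60L, 30L, 31L)
  out <- derive_features(co, tab)
  expect_equal(as.character(out$age_band),
               c("0-17", "0-17", "18-65", "18-65", ">65", ">65"))
  expect_equal(out$long_stay, c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE))
})
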