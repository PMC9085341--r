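test_that("category merging equals the brute-force best partition (nominal)", {
  set.seed(41)
  for (r in 1:40) {
    k <- sample(3:4, 1)
    cats <- sample(letters[1:k], 12, replace = TRUE)
    while (length(unique(cats)) < k) cats <- sample(letters[1:k], 12, replace = TRUE)
    values <- rnorm(12, mean = as.integer(factor(cats)))
    got <- merge_categories(values, cats, "nominal")
    oracle <- oracle_best_partition(values, cats, "nominal")
    expect_equal(canon_partition(got$groups), canon_partition(oracle$partition))
    expect_equal(got$p, oracle$p, tolerance = 1e-8)
  }
})

test_that("category merging equals the brute-force best partition (ordinal)", {
  set.seed(43)
  for (r in 1:25) {
    cats <- as.character(sample(1:4, 12, replace = TRUE))
    while (length(unique(cats)) < 4) cats <- as.character(sample(1:4, 12, replace = TRUE))
    values <- rnorm(12, mean = as.integer(cats))
    got <- merge_categories(values, factor(cats, levels = as.character(1:4)),
                            "ordinal")
    oracle <- oracle_best_partition(values, cats, "ordinal")
    expect_equal(canon_partition(got$groups), canon_partition(oracle$partition))
    # ordinal merging only fuses adjacent levels
    for (g in got$groups) {
      idx <- sort(as.integer(g))
      expect_equal(idx, seq(min(idx), max(idx)))
    }
  }
})

test_that("clear separation merges the two alike categories", {
  values <- c(0.01, -0.02, 0, 0.02, 10, 10.01)
  cats <- c("a", "a", "b", "b", "c", "c")
  got <- merge_categories(values, cats, "nominal")
  expect_equal(canon_partition(got$groups), "a+b|c")
  # identical multisets across categories: p stays ~1, nothing to split on
  same <- merge_categories(c(1, 2, 1, 2), c("a", "a", "b", "b"), "nominal")
  expect_gt(same$p, 0.9)
  expect_error(merge_categories(1:3, c("a", "a", "a")), "two categories")
})

test_that("Bonferroni adjustment is a true partition count and never shrinks p", {
  set.seed(47)
  df <- data.frame(total_cost = rgamma(200, 2, 1e-3),
                   bin = sample(c("x", "y"), 200, replace = TRUE),
                   four = sample(letters[1:4], 200, replace = TRUE),
                   stringsAsFactors = FALSE)
  cfg <- tree_config(predictors = c(bin = "nominal", four = "nominal"),
                     alpha_split = 0.9999, min_parent_n = 10, min_child_n = 5)
  # binary predictor: only one partition, multiplier 1, adjusted = raw
  mc <- merge_categories(df$total_cost, df$bin, "nominal")
  sp <- select_split(df, tree_config(predictors = c(bin = "nominal"),
                                     alpha_split = 0.9999,
                                     min_parent_n = 10, min_child_n = 5))
  expect_equal(sp$p_adj, sp$p_raw, tolerance = 1e-12)
  expect_equal(sp$p_raw, mc$p, tolerance = 1e-12)
  # multi-category: adjusted >= raw always
  spf <- select_split(df, cfg)
  expect_gte(spf$p_adj, spf$p_raw - 1e-12)
})

test_that("the perfectly separating predictor wins the split", {
  set.seed(53)
  n <- 200
  signal <- sample(c("lo", "hi"), n, replace = TRUE)
  df <- data.frame(
    total_cost = ifelse(signal == "hi", 100, 10) + rnorm(n),
    signal = signal,
    noise1 = sample(letters[1:3], n, replace = TRUE),
    noise2 = sample(c("u", "v"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  cfg <- tree_config(predictors = c(noise1 = "nominal", signal = "nominal",
                                    noise2 = "nominal"),
                     min_parent_n = 20, min_child_n = 10)
  sp <- select_split(df, cfg)
  expect_equal(sp$predictor, "signal")
  # all-constant predictors: nothing to split
  df2 <- df
  df2$signal <- "same"
  df2$noise1 <- "same"
  df2$noise2 <- "same"
  expect_null(select_split(df2, cfg))
})

test_that("the grown tree partitions the cohort and obeys its thresholds", {
  co <- study_cohort()
  tr <- grow_tree(co)
  expect_equal(sum(tr$leaves$n), nrow(co))
  expect_true(all(table(tree_groups(tr)) == tr$leaves$n))
  # children sizes sum to parents'
  for (id in names(tr$splits)) {
    kids <- tr$splits[[id]]$children
    expect_equal(sum(tr$nodes$n[tr$nodes$id %in% kids]),
                 tr$nodes$n[tr$nodes$id == as.integer(id)])
  }
  internal <- tr$nodes[!tr$nodes$is_leaf, ]
  expect_true(all(internal$p_adj <= tr$config$alpha_split))
  expect_true(all(tr$leaves$n >= tr$config$min_child_n))
  # the severity level, the strongest configured effect, splits the root
  expect_equal(tr$nodes$split_predictor[tr$nodes$id == 1], "cc_level")
})

test_that("tree growth is invariant to record order and constant cost gives one leaf", {
  co <- study_cohort()[1:1500, ]
  tr1 <- grow_tree(co)
  set.seed(99)
  perm <- sample(nrow(co))
  tr2 <- grow_tree(co[perm, ])
  expect_equal(tr1$leaves$label, tr2$leaves$label)
  expect_equal(tr1$leaves$n, tr2$leaves$n)
  expect_equal(tree_groups(tr1), tree_groups(tr2)[order(perm)])
  co$total_cost <- 1000
  expect_equal(nrow(grow_tree(co)$leaves), 1)
})

test_that("raising alpha never yields fewer leaves", {
  co <- study_cohort()[1:3000, ]
  leaves <- vapply(c(1e-6, 1e-3, 0.05, 0.2), function(a) {
    nrow(grow_tree(co, tree_config(alpha_split = a))$leaves)
  }, numeric(1))
  expect_true(all(diff(leaves) >= 0))
})

test_that("CART splits match the exhaustive SSE oracle on small nodes", {
  set.seed(61)
  for (r in 1:20) {
    n <- sample(10:20, 1)
    df <- data.frame(
      total_cost = round(rgamma(n, 2, 1e-3), 2),
      p1 = sample(letters[1:3], n, replace = TRUE),
      p2 = sample(c("x", "y"), n, replace = TRUE),
      p3 = sample(LETTERS[1:4], n, replace = TRUE),
      stringsAsFactors = FALSE)
    cfg <- tree_config(algorithm = "cart", max_depth = 1, min_parent_n = 4,
                       min_child_n = 2, cp = 0,
                       predictors = c(p1 = "nominal", p2 = "nominal",
                                      p3 = "nominal"))
    tr <- grow_cart(df, cfg)
    oracle <- oracle_best_binary_split(df, c("p1", "p2", "p3"))
    if (nrow(tr$leaves) == 1) next
    sp <- tr$splits[["1"]]
    got_sse <- sum(vapply(seq_along(sp$groups), function(j) {
      v <- df$total_cost[df[[sp$predictor]] %in% sp$groups[[j]]]
      sum((v - mean(v))^2)
    }, numeric(1)))
    # same SSE optimum (the argmin may tie across predictors)
    expect_equal(got_sse, oracle$sse, tolerance = 1e-6)
  }
})

test_that("CART agrees with rpart on a clean two-level signal", {
  skip_if_not_installed("rpart")
  co <- study_cohort()
  cfg <- tree_config(algorithm = "cart", max_depth = 1, min_parent_n = 100,
                     min_child_n = 50, cp = 0.001)
  tr <- grow_cart(co, cfg)
  rp <- rpart::rpart(total_cost ~ cc_level, data = co, method = "anova",
                     control = rpart::rpart.control(maxdepth = 1, cp = 0.001,
                                                    minsplit = 100,
                                                    minbucket = 50))
  expect_equal(tr$splits[["1"]]$predictor, "cc_level")
  # both should isolate the same side at the root
  rp_left <- attr(rp$splits, "dimnames")[[1]][1]
  expect_equal(rp_left, "cc_level")
})

test_that("deeper CART trees never increase training SSE", {
  co <- study_cohort()[1:2500, ]
  sse_of <- function(depth) {
    tr <- grow_cart(co, tree_config(algorithm = "cart", max_depth = depth,
                                    cp = 0, min_parent_n = 100, min_child_n = 50))
    pred <- tr$leaves$mean_cost[match(tr$leaf_of, tr$leaves$id)]
    sum((co$total_cost - pred)^2)
  }
  sses <- vapply(1:4, sse_of, numeric(1))
  expect_true(all(diff(sses) <= 1e-6))
})

test_that("model comparison reports sane metrics and degenerate flags", {
  co <- study_cohort()
  tr <- grow_tree(co)
  ct <- grow_cart(co, tree_config(algorithm = "cart", max_depth = 1))
  cmp <- compare_models(list(tr, ct), co)
  expect_true(all(cmp$linear_correlation >= -1 & cmp$linear_correlation <= 1))
  expect_true(all(cmp$mean_absolute_error >= 0))
  expect_equal(cmp$n_groups[1], nrow(tr$leaves))
  # the finer E-CHAID grouping explains at least as much as depth-1 CART
  expect_gte(cmp$linear_correlation[1], cmp$linear_correlation[2])
  # single-leaf model: correlation reported as 0 and flagged
  co2 <- co[1:500, ]
  co2$total_cost <- 777
  tr1 <- grow_tree(co2)
  cmp1 <- compare_models(list(tr1), co2)
  expect_equal(cmp1$linear_correlation, 0)
  expect_true(cmp1$degenerate)
  expect_equal(cmp1$mean_absolute_error, 0)
})

test_that("trees serialise to JSON and back", {
  co <- study_cohort()[1:2000, ]
  tr <- grow_tree(co)
  path <- withr::local_tempfile(fileext = ".json")
  tree_to_json(tr, path)
  back <- tree_from_json(path)
  expect_equal(back$algorithm, "echaid")
  expect_equal(nrow(back$leaves), nrow(tr$leaves))
  expect_equal(back$leaves$label, tr$leaves$label)
  expect_equal(sort(names(back$splits)), sort(names(tr$splits)))
  for (id in names(tr$splits)) {
    expect_equal(back$splits[[id]]$predictor, tr$splits[[id]]$predictor)
  }
})
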