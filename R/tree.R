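# Cost-grouping regression trees over categorical predictors.
#
# The primary algorithm is exhaustive CHAID for a continuous target:
# categories of each candidate predictor are merged pairwise, always fusing
# the least-significantly-different admissible pair (any pair for nominal
# predictors, adjacent only for ordinal), while remembering the one-way
# ANOVA p-value of every intermediate partition; the best-remembered
# partition competes across predictors after a Bonferroni adjustment equal
# to the number of ways the predictor's observed categories can be
# partitioned into that many merged groups. The CART baseline makes binary
# splits maximising the within-node sum-of-squares reduction over all binary
# category partitions.

#' Tree-growing configuration
#'
#' @param algorithm `"echaid"` or `"cart"`.
#' @param alpha_split Significance level a Bonferroni-adjusted split p-value
#'   must reach (E-CHAID; default 0.05).
#' @param bonferroni Apply the partition-count Bonferroni multiplier
#'   (default `TRUE`).
#' @param max_depth Maximum tree depth (root = 0; default 5).
#' @param min_parent_n Minimum node size eligible for splitting (default
#'   100).
#' @param min_child_n Minimum size of every child a split may create
#'   (default 50).
#' @param cp CART only: minimum split improvement as a fraction of the root
#'   sum of squares (default 0.01, the conventional complexity threshold).
#' @param predictors Named character vector: predictor column -> scale
#'   (`"nominal"` or `"ordinal"`). Order breaks ties in adjusted p-values.
#'   The default uses the significant adjusted cost drivers, with age bands
#'   ordinal; the long-stay indicator is deliberately not a grouping
#'   variable.
#' @param target Response column (default `"total_cost"`).
#' @return Object of class `drg_tree_config`.
#' @export
tree_config <- function(algorithm = c("echaid", "cart"),
                        alpha_split = 0.05,
                        bonferroni = TRUE,
                        max_depth = 5,
                        min_parent_n = 100,
                        min_child_n = 50,
                        cp = 0.01,
                        predictors = c(cc_level = "nominal",
                                       discharge_mode = "nominal",
                                       age_band = "ordinal",
                                       sex = "nominal",
                                       admission_route = "nominal"),
                        target = "total_cost") {
  algorithm <- match.arg(algorithm)
  stopifnot(alpha_split > 0, alpha_split < 1,
            min_child_n >= 1, min_parent_n >= 2 * min_child_n,
            all(predictors %in% c("nominal", "ordinal")))
  structure(list(algorithm = algorithm, alpha_split = alpha_split,
                 bonferroni = bonferroni, max_depth = max_depth,
                 min_parent_n = min_parent_n, min_child_n = min_child_n,
                 cp = cp, predictors = predictors, target = target),
            class = "drg_tree_config")
}

# One-way ANOVA F and p for values grouped by g (integer/character vector).
# The p-value is also carried on the log scale: split tests on strong
# effects underflow double precision, and partitions must still be ranked.
anova_stats <- function(values, g) {
  g <- as.character(g)
  n <- length(values)
  k <- length(unique(g))
  if (k < 2 || n <= k) {
    return(list(F = 0, p = 1, logp = 0, df1 = k - 1, df2 = n - k))
  }
  gm <- mean(values)
  means <- tapply(values, g, mean)
  sizes <- tapply(values, g, length)
  ssb <- sum(sizes * (means - gm)^2)
  ssw <- sum((values - means[g])^2)
  df1 <- k - 1
  df2 <- n - k
  if (ssw <= 1e-12 * max(ssb, 1)) {
    if (ssb <= 1e-12) return(list(F = 0, p = 1, logp = 0, df1 = df1, df2 = df2))
    return(list(F = Inf, p = 0, logp = -Inf, df1 = df1, df2 = df2))
  }
  f <- (ssb / df1) / (ssw / df2)
  logp <- stats::pf(f, df1, df2, lower.tail = FALSE, log.p = TRUE)
  list(F = f, p = exp(logp), logp = logp, df1 = df1, df2 = df2)
}

# Map each observation's category to its merged-group index.
group_assignment <- function(categories, groups) {
  idx <- integer(length(categories))
  for (j in seq_along(groups)) idx[categories %in% groups[[j]]] <- j
  idx
}

# All set partitions of `items` (list of lists of character vectors).
set_partitions <- function(items) {
  if (length(items) == 1) return(list(list(items)))
  rest <- set_partitions(items[-1])
  out <- list()
  for (p in rest) {
    for (j in seq_along(p)) {
      q <- p
      q[[j]] <- c(items[1], q[[j]])
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(list(items[1]), p)
  }
  out
}

# Contiguous-interval partitions of ordered `items` (cut-point subsets).
interval_partitions <- function(items) {
  c_cats <- length(items)
  out <- list()
  for (mask in 0:(2^(c_cats - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(seq_len(c_cats - 1) - 1)) > 0)
    bounds <- c(0, cuts, c_cats)
    out[[length(out) + 1L]] <-
      lapply(seq_len(length(bounds) - 1),
             function(j) items[(bounds[j] + 1):bounds[j + 1]])
  }
  out
}

#' Exhaustive CHAID category merging for a continuous target
#'
#' Finds the merged partition of a predictor's observed categories whose
#' one-way ANOVA against the target is most significant. For predictors
#' with up to `exhaustive_limit` categories (which covers every predictor
#' in this domain) the search scores every admissible partition - all set
#' partitions for a nominal predictor, all contiguous-interval partitions
#' for an ordinal one - so the returned partition is the exact optimum.
#' Beyond the limit it falls back to the classical sequential scheme:
#' repeatedly merge the admissible pair of groups (any pair if nominal,
#' adjacent if ordinal) whose two-group ANOVA comparison is least
#' significant, remembering the best partition seen.
#'
#' @param values Numeric target values.
#' @param categories Category of each value (character or factor; factor
#'   level order defines ordinal adjacency).
#' @param scale `"nominal"` or `"ordinal"`.
#' @param exhaustive_limit Maximum category count for the exact partition
#'   search (default 6; Bell(6) = 203 partitions).
#' @return List: `groups` (list of character vectors, the merged partition),
#'   `p` (its one-way ANOVA p), `statistic` (its F), `n_groups`,
#'   `n_categories` (observed categories before merging).
#' @export
merge_categories <- function(values, categories, scale = c("nominal", "ordinal"),
                             exhaustive_limit = 6) {
  scale <- match.arg(scale)
  if (is.factor(categories)) {
    lev <- levels(droplevels(categories))
    categories <- as.character(categories)
  } else {
    categories <- as.character(categories)
    lev <- unique(categories)
    if (scale == "ordinal") lev <- sort(lev)
  }
  counts <- table(factor(categories, levels = lev))
  if (any(counts == 0)) stop_input("every category must be nonempty")
  if (length(lev) < 2) stop_input("need at least two categories")

  best <- NULL
  consider <- function(groups) {
    a <- anova_stats(values, group_assignment(categories, groups))
    # Rank partitions on the log scale; genuine ties prefer the coarser
    # partition, then first-seen order.
    better <- is.null(best)
    if (!better) {
      d <- a$logp - best$logp
      if (is.nan(d)) d <- 0  # both partitions underflow identically
      better <- d < -1e-10 ||
        (abs(d) <= 1e-10 && length(groups) < length(best$groups))
    }
    if (better) {
      best <<- list(groups = groups, p = a$p, logp = a$logp, statistic = a$F)
    }
  }

  if (length(lev) <= exhaustive_limit) {
    parts <- if (scale == "ordinal") interval_partitions(lev)
             else set_partitions(as.list(lev))
    for (p in parts) {
      if (length(p) >= 2) consider(lapply(p, unlist))
    }
  } else {
    groups <- as.list(lev)
    repeat {
      consider(groups)
      if (length(groups) == 2) break
      pairs <- if (scale == "ordinal") {
        cbind(seq_len(length(groups) - 1), seq_len(length(groups) - 1) + 1)
      } else {
        t(utils::combn(length(groups), 2))
      }
      pvals <- apply(pairs, 1, function(pr) {
        keep <- categories %in% c(groups[[pr[1]]], groups[[pr[2]]])
        anova_stats(values[keep],
                    categories[keep] %in% groups[[pr[2]]])$logp
      })
      pick <- which.max(pvals)
      i <- pairs[pick, 1]
      j <- pairs[pick, 2]
      groups[[i]] <- c(groups[[i]], groups[[j]])
      groups[[j]] <- NULL
    }
  }
  list(groups = best$groups, p = best$p, logp = best$logp,
       statistic = best$statistic,
       n_groups = length(best$groups), n_categories = length(lev))
}

# Bonferroni multiplier: number of ways to partition c observed categories
# into k merged groups (nominal: Stirling number of the second kind;
# ordinal: choice of k-1 cut points among c-1 gaps).
bonferroni_multiplier <- function(c_cats, k_groups, scale) {
  if (scale == "ordinal") choose(c_cats - 1, k_groups - 1)
  else stirling2(c_cats, k_groups)
}

#' Select the best E-CHAID split for a node
#'
#' Runs [merge_categories()] for every candidate predictor, Bonferroni-
#' adjusts each predictor's best-partition p-value by its partition count,
#' and returns the predictor with the smallest adjusted p-value provided it
#' reaches `alpha_split` and every child meets `min_child_n`. Ties are
#' broken by predictor order.
#'
#' @param data Node data frame holding the target and predictor columns.
#' @param config A [tree_config()].
#' @return List (`predictor`, `groups`, `p_raw`, `p_adj`, `statistic`) or
#'   `NULL` when no admissible split exists.
#' @export
select_split <- function(data, config = tree_config()) {
  values <- data[[config$target]]
  best <- NULL
  for (pred in names(config$predictors)) {
    x <- data[[pred]]
    if (is.logical(x)) x <- ifelse(x, "yes", "no")
    if (is.factor(x)) x <- droplevels(x)
    obs <- if (is.factor(x)) levels(x) else unique(as.character(x))
    if (length(obs) < 2) next
    scale <- config$predictors[[pred]]
    mc <- merge_categories(values, x, scale)
    sizes <- tabulate(group_assignment(as.character(x), mc$groups),
                      nbins = mc$n_groups)
    if (any(sizes < config$min_child_n)) next
    mult <- if (config$bonferroni) {
      bonferroni_multiplier(mc$n_categories, mc$n_groups, scale)
    } else 1
    logp_adj <- min(0, mc$logp + log(mult))
    better <- is.null(best)
    if (!better) {
      d <- logp_adj - best$logp_adj
      if (is.nan(d)) d <- 0
      better <- d < 0  # ties keep the earlier predictor in declared order
    }
    if (better) {
      best <- list(predictor = pred, groups = mc$groups, p_raw = mc$p,
                   p_adj = exp(logp_adj), logp_adj = logp_adj,
                   statistic = mc$statistic)
    }
  }
  if (is.null(best) || best$logp_adj > log(config$alpha_split)) return(NULL)
  best
}

# Best CART binary split for one node: maximise SSE reduction over all
# binary partitions of every predictor's observed categories.
select_split_cart <- function(data, config) {
  values <- data[[config$target]]
  node_sse <- sum((values - mean(values))^2)
  best <- NULL
  for (pred in names(config$predictors)) {
    x <- data[[pred]]
    if (is.logical(x)) x <- ifelse(x, "yes", "no")
    if (is.factor(x)) {
      lev <- levels(droplevels(x))
      x <- as.character(x)
    } else {
      x <- as.character(x)
      lev <- unique(x)
      if (config$predictors[[pred]] == "ordinal") lev <- sort(lev)
    }
    c_cats <- length(lev)
    if (c_cats < 2) next
    partitions <- if (config$predictors[[pred]] == "ordinal") {
      lapply(seq_len(c_cats - 1), function(cut) lev[seq_len(cut)])
    } else {
      # Fix lev[1] on the left to enumerate each bipartition once.
      out <- list()
      rest <- lev[-1]
      for (mask in 0:(2^(c_cats - 1) - 1)) {
        out[[length(out) + 1L]] <- c(lev[1], rest[bitwAnd(mask, 2^(seq_along(rest) - 1)) > 0])
      }
      out
    }
    for (left in partitions) {
      inl <- x %in% left
      nl <- sum(inl)
      nr <- length(x) - nl
      if (nl < config$min_child_n || nr < config$min_child_n) next
      sse <- sum((values[inl] - mean(values[inl]))^2) +
        sum((values[!inl] - mean(values[!inl]))^2)
      red <- node_sse - sse
      if (is.null(best) || red > best$reduction + 1e-9) {
        best <- list(predictor = pred,
                     groups = list(left, setdiff(lev, left)),
                     reduction = red, p_raw = NA_real_, p_adj = NA_real_,
                     statistic = red)
      }
    }
  }
  best
}

grow <- function(cohort, config) {
  for (pred in names(config$predictors)) {
    if (!(pred %in% names(cohort))) stop_input("predictor '", pred, "' absent from cohort")
  }
  if (nrow(cohort) == 0) stop_input("empty cohort")
  values <- cohort[[config$target]]
  root_sse <- sum((values - mean(values))^2)

  nodes <- list()
  splits <- list()
  leaf_of <- integer(nrow(cohort))
  next_id <- 1L

  new_node <- function(parent, depth, rows, label) {
    id <- next_id
    next_id <<- next_id + 1L
    nodes[[id]] <<- list(id = id, parent = parent, depth = depth,
                         n = length(rows), mean = mean(values[rows]),
                         median = stats::median(values[rows]),
                         label = label, predictor = NA_character_,
                         p_adj = NA_real_, statistic = NA_real_,
                         is_leaf = TRUE)
    id
  }

  grow_node <- function(id, rows, depth, path) {
    if (length(rows) < config$min_parent_n || depth >= config$max_depth) return()
    data <- cohort[rows, , drop = FALSE]
    cand <- if (config$algorithm == "echaid") {
      select_split(data, config)
    } else {
      sc <- select_split_cart(data, config)
      if (!is.null(sc) && sc$reduction <= config$cp * root_sse) sc <- NULL
      sc
    }
    if (is.null(cand)) return()
    x <- data[[cand$predictor]]
    if (is.logical(x)) x <- ifelse(x, "yes", "no")
    x <- as.character(x)
    nodes[[id]]$is_leaf <<- FALSE
    nodes[[id]]$predictor <<- cand$predictor
    nodes[[id]]$p_adj <<- cand$p_adj
    nodes[[id]]$statistic <<- cand$statistic
    child_ids <- integer(length(cand$groups))
    for (j in seq_along(cand$groups)) {
      seg <- paste0(cand$predictor, "=", paste(cand$groups[[j]], collapse = "/"))
      sub <- rows[x %in% cand$groups[[j]]]
      child_ids[j] <- new_node(id, depth + 1L, sub,
                               paste(c(path, seg), collapse = "; "))
      grow_node(child_ids[j], sub, depth + 1L, c(path, seg))
    }
    splits[[as.character(id)]] <<- list(predictor = cand$predictor,
                                        p_adj = cand$p_adj,
                                        p_raw = cand$p_raw,
                                        statistic = cand$statistic,
                                        children = child_ids,
                                        groups = cand$groups)
  }

  assign_rows <- function(id, rows) {
    sp <- splits[[as.character(id)]]
    if (is.null(sp)) {
      leaf_of[rows] <<- id
      return()
    }
    x <- cohort[[sp$predictor]][rows]
    if (is.logical(x)) x <- ifelse(x, "yes", "no")
    x <- as.character(x)
    for (j in seq_along(sp$children)) {
      assign_rows(sp$children[j], rows[x %in% sp$groups[[j]]])
    }
  }

  root <- new_node(NA_integer_, 0L, seq_len(nrow(cohort)), "<root>")
  grow_node(root, seq_len(nrow(cohort)), 0L, character(0))
  assign_rows(root, seq_len(nrow(cohort)))

  node_df <- do.call(rbind, lapply(nodes, function(nd) {
    data.frame(id = nd$id, parent = nd$parent, depth = nd$depth, n = nd$n,
               mean_cost = nd$mean, median_cost = nd$median,
               split_predictor = nd$predictor, p_adj = nd$p_adj,
               statistic = nd$statistic, is_leaf = nd$is_leaf,
               label = nd$label, stringsAsFactors = FALSE)
  }))
  leaf_ids <- node_df$id[node_df$is_leaf]
  leaves <- node_df[node_df$is_leaf,
                    c("id", "label", "n", "mean_cost", "median_cost")]
  leaves$group <- seq_len(nrow(leaves))
  rownames(leaves) <- NULL
  structure(list(algorithm = config$algorithm, nodes = node_df,
                 splits = splits, leaves = leaves,
                 leaf_of = leaf_of, config = config),
            class = "drg_tree")
}

#' Grow the exhaustive-CHAID cost-grouping tree
#'
#' Recursively applies [select_split()] until no split is admissible or the
#' depth/size limits are reached. Deterministic given the data and
#' configuration; record order does not matter.
#'
#' @param cohort Cleaned cohort with derived features.
#' @param config A [tree_config()] (its `algorithm` is forced to
#'   `"echaid"`).
#' @return Object of class `drg_tree`: `nodes` (one row per node), `splits`,
#'   `leaves` (stable group numbering with path labels), `leaf_of`
#'   (leaf node id per record).
#' @export
grow_tree <- function(cohort, config = tree_config()) {
  config$algorithm <- "echaid"
  grow(cohort, config)
}

#' Grow the CART baseline tree
#'
#' Binary splits maximise the reduction in within-node sum of squares over
#' every binary partition of each predictor's categories, subject to the
#' same size limits and a minimum improvement of `cp` times the root sum of
#' squares.
#'
#' @inheritParams grow_tree
#' @return A `drg_tree` (see [grow_tree()]).
#' @export
grow_cart <- function(cohort, config = tree_config(algorithm = "cart")) {
  config$algorithm <- "cart"
  grow(cohort, config)
}

#' @export
print.drg_tree <- function(x, ...) {
  cat(toupper(x$algorithm), "cost-grouping tree:", nrow(x$leaves), "groups,",
      sum(x$leaves$n), "records\n")
  for (i in seq_len(nrow(x$leaves))) {
    cat(sprintf("  group %d (n = %d, median %.2f): %s\n", x$leaves$group[i],
                x$leaves$n[i], x$leaves$median_cost[i], x$leaves$label[i]))
  }
  invisible(x)
}

#' Per-record group labels from a fitted tree
#'
#' @param tree A `drg_tree`.
#' @return Integer vector of group numbers (1..number of leaves), one per
#'   training record.
#' @export
tree_groups <- function(tree) {
  match(tree$leaf_of, tree$leaves$id)
}

#' Compare fitted grouping models on their training cohort
#'
#' Predictions are leaf mean costs. Reports the Pearson correlation between
#' predicted and observed cost, the mean absolute error, the standard
#' deviation of the errors, and the number of groups. A single-leaf model
#' has no prediction variance; its correlation is reported as 0 and flagged.
#'
#' @param models List of `drg_tree` objects fitted on `cohort`.
#' @param cohort The training cohort.
#' @return Data frame, one row per model.
#' @export
compare_models <- function(models, cohort) {
  rows <- lapply(models, function(m) {
    obs <- cohort[[m$config$target]]
    pred <- m$leaves$mean_cost[match(m$leaf_of, m$leaves$id)]
    err <- obs - pred
    degenerate <- stats::sd(pred) == 0
    data.frame(
      model = m$algorithm,
      linear_correlation = if (degenerate) 0 else stats::cor(pred, obs),
      mean_absolute_error = mean(abs(err)),
      sd_error = stats::sd(err),
      n_groups = nrow(m$leaves),
      degenerate = degenerate,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Serialise a fitted tree to JSON
#'
#' The structure (nodes, splits with merged-category maps, leaf table) is
#' written; the per-record assignment travels with the cohort file as a
#' group column instead.
#'
#' @param tree A `drg_tree`.
#' @param path Optional file path; when omitted the JSON string is returned.
#' @export
tree_to_json <- function(tree, path = NULL) {
  payload <- list(
    algorithm = tree$algorithm,
    nodes = tree$nodes,
    splits = lapply(tree$splits, function(sp) {
      list(predictor = sp$predictor, p_adj = sp$p_adj, p_raw = sp$p_raw,
           statistic = sp$statistic, children = sp$children,
           groups = sp$groups)
    }),
    leaves = tree$leaves
  )
  js <- jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, null = "null", na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read a tree structure back from JSON
#'
#' @param path File path or JSON string from [tree_to_json()].
#' @return List with `algorithm`, `nodes`, `splits` and `leaves` (structure
#'   only; no per-record assignment).
#' @export
tree_from_json <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  payload$splits <- lapply(payload$splits, function(sp) {
    sp$groups <- lapply(sp$groups, as.character)
    sp
  })
  payload
}

#' Write the model-comparison report
#'
#' @param comparison A [compare_models()] result.
#' @param path Output path (tab-delimited).
#' @export
write_comparison_report <- function(comparison, path) {
  out <- comparison
  out$linear_correlation <- round(out$linear_correlation, 3)
  out$mean_absolute_error <- round(out$mean_absolute_error, 3)
  out$sd_error <- round(out$sd_error, 3)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
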