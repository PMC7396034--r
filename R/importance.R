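#' Rank features by out-of-bag permutation importance
#'
#' Importance-based feature sorting for the selection stage. A bagged-tree
#' model (the package's own [fit_bagging()] ensemble of CART trees) is fit
#' to the table; each feature's score is the mean decrease in out-of-bag
#' accuracy when that feature is permuted among each tree's out-of-bag rows,
#' clamped at zero. Pure-noise features therefore score approximately 0 and
#' informative features rank above them. Deterministic for a fixed seed.
#'
#' @param table A cleaned [feature_table] (no missing cells) with at least
#'   two features and both classes present.
#' @param seed Integer seed.
#' @param n_trees Ensemble size for the importance model (default 20).
#' @param max_depth,min_leaf CART controls (defaults 8 and 5).
#' @return An object of class `importance_ranking`: `scores` (named,
#'   nonnegative, in column order) and `ordering` (feature names by
#'   descending score; ties broken by column order).
#' @export
rank_feature_importance <- function(table, seed = 1L, n_trees = 20L,
                                    max_depth = 8L, min_leaf = 5L) {
  stopifnot(inherits(table, "feature_table"))
  if (n_features(table) < 2L) stop_config("at least two features required")
  if (length(unique(table$label)) < 2L) {
    stop_config("degenerate labels: only one class present")
  }
  if (anyNA(table$values)) {
    stop_config("rank_feature_importance requires a cleaned table (no missing cells)")
  }
  x <- table$values
  y <- ifelse(table$label == 1L, 1L, -1L)
  n <- nrow(x)
  p <- ncol(x)

  seeds <- derive_seeds(seed, 2L)
  model <- fit_bagging(x, y, n_learners = n_trees, seed = seeds[1L],
                       max_depth = max_depth, min_leaf = min_leaf)

  drops <- matrix(0, n_trees, p)
  used <- rep(FALSE, n_trees)
  with_seed(seeds[2L], {
    for (t in seq_len(n_trees)) {
      oob <- setdiff(seq_len(n), unique(model$in_bag[[t]]))
      if (length(oob) < 2L) next
      used[t] <- TRUE
      tree <- model$learners[[t]]
      x_oob <- x[oob, , drop = FALSE]
      base_acc <- mean(predict(tree, x_oob) == y[oob])
      for (j in seq_len(p)) {
        x_perm <- x_oob
        x_perm[, j] <- x_perm[sample.int(length(oob)), j]
        drops[t, j] <- base_acc - mean(predict(tree, x_perm) == y[oob])
      }
    }
  })
  if (!any(used)) stop_config("no out-of-bag rows available for importance")
  scores <- pmax(colMeans(drops[used, , drop = FALSE]), 0)
  names(scores) <- colnames(x)
  ordering <- colnames(x)[order(-scores, seq_len(p))]
  structure(list(scores = scores, ordering = ordering),
            class = "importance_ranking")
}

#' @export
print.importance_ranking <- function(x, ...) {
  cat("<importance_ranking> top features:\n")
  print(utils::head(x$scores[x$ordering], 10L))
  invisible(x)
}

#' Keep the top-k features of a ranking
#'
#' Subsets the table to the `k` most important features, in ranking order
#' (so downstream grid encoding places the most important feature first).
#' An optional `keep` list of feature names is forced into the selection
#' ahead of the ranking — a stand-in for domain-expert screening.
#'
#' @param table A [feature_table].
#' @param ranking An `importance_ranking` over the table's columns.
#' @param k Number of features to keep (default 36, a full 6x6 grid).
#' @param keep Optional character vector of feature names to retain
#'   regardless of rank.
#' @return A [feature_table] with `k` columns in importance order (forced
#'   `keep` columns first); the label is untouched.
#' @export
select_features <- function(table, ranking, k = 36L, keep = NULL) {
  stopifnot(inherits(table, "feature_table"),
            inherits(ranking, "importance_ranking"))
  if (k > n_features(table)) {
    stop_config("k = ", k, " exceeds the number of features (",
                n_features(table), ")")
  }
  keep <- unique(keep)
  unknown <- setdiff(keep, colnames(table$values))
  if (length(unknown)) {
    stop_config("keep-list names not in table: ", paste(unknown, collapse = ", "))
  }
  if (length(keep) > k) stop_config("keep-list longer than k")
  chosen <- c(keep, setdiff(ranking$ordering, keep))[seq_len(k)]
  ft_cols(table, chosen)
}
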