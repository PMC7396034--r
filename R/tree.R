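#' Fit a CART-style decision tree
#'
#' Binary classification tree over numeric features with labels in
#' `{-1, +1}`: axis-aligned splits chosen by minimum weighted Gini impurity,
#' split values at midpoints between consecutive distinct sorted values,
#' depth and minimum-leaf-size stopping. Leaves predict the majority label,
#' with ties broken towards `+1`. Ties in the split search are broken
#' deterministically (first feature in column order, then smallest
#' threshold), so fitting is fully deterministic.
#'
#' This is the package's default base learner for the bagging ensemble.
#'
#' @param x Numeric matrix of features (n x p).
#' @param y Labels in `{-1, +1}`, length n.
#' @param max_depth Maximum tree depth (root = depth 0; default 8).
#' @param min_leaf Minimum rows per leaf (default 5).
#' @return An object of class `cart_tree` with a [predict][predict.cart_tree]
#'   method returning labels in `{-1, +1}`.
#' @export
fit_decision_tree <- function(x, y, max_depth = 8L, min_leaf = 5L) {
  x <- as.matrix(x)
  if (!all(y %in% c(-1, 1))) stop_config("labels must be in {-1, +1}")
  if (nrow(x) < 1L) stop_config("at least one row required")
  node <- grow_cart(x, as.integer(y), seq_len(nrow(x)), 0L,
                    as.integer(max_depth), as.integer(min_leaf))
  structure(list(root = node, n_features = ncol(x),
                 max_depth = max_depth, min_leaf = min_leaf),
            class = "cart_tree")
}

leaf_node <- function(y_node) {
  s <- sum(y_node)
  list(leaf = TRUE, pred = if (s >= 0L) 1L else -1L, n = length(y_node))
}

grow_cart <- function(x, y, idx, depth, max_depth, min_leaf) {
  y_node <- y[idx]
  n <- length(idx)
  pos <- sum(y_node == 1L)
  if (pos == 0L || pos == n || depth >= max_depth || n < 2L * min_leaf) {
    return(leaf_node(y_node))
  }
  best <- best_split_cpp(x, y, idx, min_leaf)
  if (best$feature == 0L) return(leaf_node(y_node))
  go_left <- x[idx, best$feature] <= best$threshold
  list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
       left = grow_cart(x, y, idx[go_left], depth + 1L, max_depth, min_leaf),
       right = grow_cart(x, y, idx[!go_left], depth + 1L, max_depth, min_leaf))
}

#' Predict with a CART tree
#'
#' @param object A `cart_tree`.
#' @param x Numeric matrix of features.
#' @param ... Unused.
#' @return Integer labels in `{-1, +1}`.
#' @export
predict.cart_tree <- function(object, x, ...) {
  x <- as.matrix(x)
  if (ncol(x) != object$n_features) {
    stop_config("feature-width mismatch: tree expects ", object$n_features,
                " columns, got ", ncol(x))
  }
  out <- integer(nrow(x))
  descend <- function(node, rows) {
    if (!length(rows)) return(invisible(NULL))
    if (node$leaf) {
      out[rows] <<- node$pred
      return(invisible(NULL))
    }
    go_left <- x[rows, node$feature] <= node$threshold
    descend(node$left, rows[go_left])
    descend(node$right, rows[!go_left])
  }
  descend(object$root, seq_len(nrow(x)))
  out
}
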