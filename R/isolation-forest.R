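#' Average unsuccessful-search path length
#'
#' The normalizing constant of the isolation-forest anomaly score:
#' `c(m) = 2 * H(m - 1) - 2 * (m - 1) / m` with `H(i) = ln(i) + gamma`
#' (Euler-Mascheroni constant), and `c(m) = 0` for `m <= 1`. For example
#' `c(2) = 2 * (ln 1 + 0.5772156649) - 1 ~= 0.1544`.
#'
#' @param m Node size(s).
#' @return Numeric vector of path-length adjustments.
#' @export
average_path_length <- function(m) {
  ifelse(m > 1, 2 * (log(m - 1) + 0.5772156649) - 2 * (m - 1) / m, 0)
}

#' Fit an isolation forest
#'
#' Grows `n_trees` random binary partition trees, each on a subsample of
#' `subsample` rows drawn without replacement (capped at n). Nodes split on
#' a uniformly random feature at a uniformly random value between that
#' feature's min and max in the node, until rows are isolated, become
#' indistinguishable, or the height limit `ceiling(log2(subsample))` is
#' reached. Anomalies — here, recording-noise outlier rows — isolate in few
#' splits and receive scores near 1.
#'
#' @param table A [feature_table] (no missing cells) with >= 2 rows.
#' @param n_trees Number of trees (default 100).
#' @param subsample Subsample size psi per tree (default 256).
#' @param seed Integer seed; identical seeds give identical forests.
#' @param contamination Fraction of rows [anomaly_filter()] will remove,
#'   in (0, 0.5) (default 0.05).
#' @return An object of class `isolation_forest`.
#' @export
fit_isolation_forest <- function(table, n_trees = 100L, subsample = 256L,
                                 seed = 1L, contamination = 0.05) {
  stopifnot(inherits(table, "feature_table"))
  n <- n_rows(table)
  if (n < 2L) stop_config("isolation forest requires >= 2 rows")
  if (anyNA(table$values)) stop_config("isolation forest requires no missing cells")
  if (contamination <= 0 || contamination >= 0.5) {
    stop_config("contamination must lie in (0, 0.5)")
  }
  psi <- min(as.integer(subsample), n)
  height_limit <- ceiling(log2(psi))
  x <- table$values
  trees <- with_seed(seed, {
    lapply(seq_len(n_trees), function(t) {
      idx <- sample.int(n, psi)
      grow_itree(x[idx, , drop = FALSE], 0L, height_limit)
    })
  })
  structure(list(trees = trees, n_trees = as.integer(n_trees), psi = psi,
                 height_limit = height_limit, contamination = contamination,
                 c_psi = average_path_length(psi),
                 columns = colnames(x)),
            class = "isolation_forest")
}

grow_itree <- function(x, depth, height_limit) {
  n <- nrow(x)
  if (n <= 1L || depth >= height_limit) return(list(size = n))
  rng <- apply(x, 2L, range)
  eligible <- which(rng[2L, ] > rng[1L, ])
  if (!length(eligible)) return(list(size = n))
  q <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
  p <- stats::runif(1L, rng[1L, q], rng[2L, q])
  left <- x[, q] < p
  list(feature = q, value = p,
       left = grow_itree(x[left, , drop = FALSE], depth + 1L, height_limit),
       right = grow_itree(x[!left, , drop = FALSE], depth + 1L, height_limit))
}

#' Isolation-forest anomaly scores
#'
#' Scores each row as `s(x) = 2^(-E[h(x)] / c(psi))` where `h(x)` is the
#' path length in a tree — the splits taken before reaching an external
#' node, plus `c(size)` for unresolved external nodes — and `c` is
#' [average_path_length()]. Scores lie in (0, 1); larger means more anomalous.
#'
#' @param model An `isolation_forest`.
#' @param table A [feature_table] with the columns the model was fit on.
#' @return Numeric vector of anomaly scores.
#' @export
anomaly_scores <- function(model, table) {
  stopifnot(inherits(model, "isolation_forest"), inherits(table, "feature_table"))
  if (!identical(colnames(table$values), model$columns)) {
    stop_config("schema mismatch: table columns differ from the fitted forest")
  }
  x <- table$values
  n <- nrow(x)
  total <- numeric(n)
  for (tree in model$trees) {
    path <- numeric(n)
    walk <- function(node, rows, depth) {
      if (!length(rows)) return(invisible(NULL))
      if (is.null(node$feature)) {
        path[rows] <<- depth + average_path_length(node$size)
        return(invisible(NULL))
      }
      left <- x[rows, node$feature] < node$value
      walk(node$left, rows[left], depth + 1L)
      walk(node$right, rows[!left], depth + 1L)
    }
    walk(tree, seq_len(n), 0L)
    total <- total + path
  }
  2^(-(total / model$n_trees) / model$c_psi)
}

#' Remove the most anomalous rows
#'
#' Drops the top `contamination` fraction of rows by anomaly score
#' (`floor(contamination * n)` rows; score ties broken by row order) and
#' reports what was removed.
#'
#' @param model An `isolation_forest`.
#' @param table A [feature_table] with matching columns.
#' @return List with `table` (the retained rows, original order) and
#'   `removed` (data frame of removed row `index` and `score`).
#' @export
anomaly_filter <- function(model, table) {
  scores <- anomaly_scores(model, table)
  n <- length(scores)
  k <- floor(model$contamination * n)
  removed_idx <- if (k > 0) utils::head(order(-scores, seq_len(n)), k) else integer(0)
  keep <- setdiff(seq_len(n), removed_idx)
  list(table = ft_rows(table, keep),
       removed = data.frame(index = removed_idx,
                            score = scores[removed_idx]))
}
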