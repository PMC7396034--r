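#' Bootstrap sample of a labeled feature set
#'
#' Draws n rows with replacement from an n-row dataset, so the output has
#' the same size as the input (~63.2% unique rows in expectation).
#'
#' @param x Numeric feature matrix.
#' @param y Label vector in `{-1, +1}`.
#' @param seed Integer seed; deterministic per seed.
#' @return List with `x`, `y` and the drawn row `indices`.
#' @export
bootstrap_sample <- function(x, y, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 1L) stop_config("empty input")
  idx <- with_seed(seed, sample.int(n, n, replace = TRUE))
  list(x = x[idx, , drop = FALSE], y = y[idx], indices = idx)
}

#' Fit a bagging ensemble
#'
#' Trains `n_learners` base classifiers, each on an independent bootstrap
#' resample of the data, for combination by sign-of-sum voting
#' (`H(x) = sign(sum_i h_i(x))`). Per-learner seeds are drawn up front from
#' `seed`, so the result does not depend on training order and identical
#' seeds give identical ensembles.
#'
#' @param x Numeric feature matrix (e.g. the n x 128 activations of the
#'   network's last dense layer).
#' @param y Labels in `{-1, +1}`, both present.
#' @param n_learners Number of base learners T (default 21, odd so
#'   sign-of-sum voting cannot tie).
#' @param learner_factory Function `(x, y, seed) -> classifier` where the
#'   classifier has a `predict(object, x)` method returning `{-1, +1}`.
#'   Defaults to the package's CART tree ([fit_decision_tree()]).
#' @param seed Integer seed.
#' @param ... Passed to the default CART factory (`max_depth`, `min_leaf`).
#' @return An object of class `bagging_ensemble`: `learners`, `seeds`,
#'   `in_bag` (per-learner bootstrap indices, used for out-of-bag
#'   permutation importance) and `n_learners`.
#' @export
fit_bagging <- function(x, y, n_learners = 21L, learner_factory = NULL,
                        seed = 1L, ...) {
  x <- as.matrix(x)
  if (n_learners < 1L) stop_config("n_learners must be >= 1")
  if (!all(y %in% c(-1, 1))) stop_config("labels must be in {-1, +1}")
  if (length(unique(y)) < 2L) stop_config("degenerate labels: only one class present")
  if (is.null(learner_factory)) {
    dots <- list(...)
    learner_factory <- function(x, y, seed) {
      do.call(fit_decision_tree, c(list(x = x, y = y), dots))
    }
  }
  seeds <- derive_seeds(seed, n_learners)
  in_bag <- vector("list", n_learners)
  learners <- vector("list", n_learners)
  for (i in seq_len(n_learners)) {
    bs <- bootstrap_sample(x, y, seed = seeds[i])
    in_bag[[i]] <- bs$indices
    learners[[i]] <- tryCatch(
      learner_factory(bs$x, bs$y, seeds[i]),
      error = function(e) stop_config("base learner ", i, " failed: ",
                                      conditionMessage(e)))
  }
  structure(list(learners = learners, n_learners = as.integer(n_learners),
                 seeds = seeds, in_bag = in_bag, n_features = ncol(x)),
            class = "bagging_ensemble")
}

#' Sign-of-sum ensemble vote
#'
#' Combines base-learner predictions by `H(x) = sign(sum_i h_i(x))`. A zero
#' sum (possible only for even T) is broken towards `+1` — the positive
#' (readmission) class, the conservative choice when recall on the positive
#' class is the priority — and counted in the `"ties"` attribute.
#'
#' @param model A `bagging_ensemble`.
#' @param x Numeric feature matrix with the width the ensemble was fit on.
#' @return Integer labels in `{-1, +1}` with attribute `ties` (number of
#'   zero-sum votes).
#' @export
vote_predict <- function(model, x) {
  stopifnot(inherits(model, "bagging_ensemble"))
  x <- as.matrix(x)
  if (ncol(x) != model$n_features) {
    stop_config("feature-width mismatch: ensemble expects ",
                model$n_features, " columns, got ", ncol(x))
  }
  votes <- vapply(model$learners, function(l) as.numeric(predict(l, x)),
                  numeric(nrow(x)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = nrow(x))
  s <- rowSums(votes)
  out <- ifelse(s < 0, -1L, 1L)
  attr(out, "ties") <- sum(s == 0)
  out
}

#' @export
predict.bagging_ensemble <- function(object, x, ...) vote_predict(object, x)

#' @export
print.bagging_ensemble <- function(x, ...) {
  cat(sprintf("<bagging_ensemble> T = %d base learners over %d features\n",
              x$n_learners, x$n_features))
  invisible(x)
}
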