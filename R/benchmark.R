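# Comparison harness: repeated stratified splits, optional balancing of the
# training split only, a roster of classifier factories, and mean/variance
# reporting per metric.

# Stratified train/test split: within each class, a seeded shuffle and an
# 80/20 cut (train_fraction configurable).
stratified_split <- function(table, train_fraction, seed) {
  with_seed(seed, {
    train_idx <- integer(0)
    for (cls in c(0L, 1L)) {
      rows <- which(table$label == cls)
      rows <- rows[sample.int(length(rows))]
      n_train <- floor(train_fraction * length(rows))
      train_idx <- c(train_idx, rows[seq_len(n_train)])
    }
    train_idx <- sort(train_idx)
    list(train = ft_rows(table, train_idx),
         test = ft_rows(table, setdiff(seq_len(n_rows(table)), train_idx)))
  })
}

# Baseline factories share a light preprocessing wrapper: pooled-median
# imputation fitted on the training split, reused at prediction time.
wrap_imputing_classifier <- function(fit_fun) {
  function(train_table, seed) {
    cleaned <- clean_table(train_table)
    medians <- apply(cleaned$values, 2L, stats::median)
    fitted <- fit_fun(cleaned$values, cleaned$label, seed)
    impute <- function(table) {
      values <- table$values[, names(medians), drop = FALSE]
      for (j in seq_len(ncol(values))) {
        miss <- is.na(values[, j])
        if (any(miss)) values[miss, j] <- medians[j]
      }
      values
    }
    structure(list(fitted = fitted, impute = impute,
                   predict_fun = attr(fitted, "predict_fun")),
              class = "baseline_model")
  }
}

#' @export
predict.baseline_model <- function(object, table, ...) {
  object$predict_fun(object$fitted, object$impute(table))
}

#' Built-in classifier factories for the benchmark
#'
#' Each factory is a function `(train_table, seed) -> model` whose model
#' has a `predict(model, table)` method returning labels in `{0, 1}` — the
#' contract [run_benchmark()] expects. Provided: the hybrid model
#' (`cnnplus`), the plain softmax CNN (`cnn`), the package's CART tree
#' (`decision_tree`), and — when the respective packages are installed —
#' `random_forest` (randomForest) and `naive_bayes` (e1071). Model
#' factories used inside the benchmark run with internal balancing
#' disabled, since the harness itself controls balancing of the training
#' split.
#'
#' @param config A `run_config` used by the CNN-based factories.
#' @return Named list of factory functions.
#' @export
benchmark_factories <- function(config = default_run_config()) {
  config$balance$enabled <- FALSE
  out <- list(
    cnnplus = function(train_table, seed) {
      train_cnnplus(train_table, config, seed = seed)
    },
    cnn = function(train_table, seed) {
      train_cnn_softmax(train_table, config, seed = seed)
    },
    decision_tree = wrap_imputing_classifier(function(x, y, seed) {
      tree <- fit_decision_tree(x, ifelse(y == 1L, 1L, -1L),
                                max_depth = config$ensemble$max_depth,
                                min_leaf = config$ensemble$min_leaf)
      attr(tree, "predict_fun") <- function(m, x) {
        as.integer(predict(m, x) == 1L)
      }
      tree
    }))
  if (requireNamespace("randomForest", quietly = TRUE)) {
    out$random_forest <- wrap_imputing_classifier(function(x, y, seed) {
      rf <- with_seed(seed, randomForest::randomForest(x, factor(y, levels = c(0, 1))))
      attr(rf, "predict_fun") <- function(m, x) {
        as.integer(as.character(predict(m, x)))
      }
      rf
    })
  }
  if (requireNamespace("e1071", quietly = TRUE)) {
    out$naive_bayes <- wrap_imputing_classifier(function(x, y, seed) {
      nb <- e1071::naiveBayes(x, factor(y, levels = c(0, 1)))
      attr(nb, "predict_fun") <- function(m, x) {
        as.integer(as.character(predict(m, x)))
      }
      nb
    })
  }
  out
}

#' Repeated-split comparison experiment
#'
#' For each classifier factory and each repetition: a fresh stratified
#' train/test split, optional oversampling balance of the training split
#' only (balancing test data would corrupt the reported metrics), fit, and
#' evaluation on the untouched test split. Reports per-run metrics plus
#' mean and variance per model. A factory failure is recorded for that
#' cell and the run continues. Fully reproducible for a fixed seed.
#'
#' @param table The full [feature_table] to split.
#' @param models Named list of factories (default [benchmark_factories()]).
#' @param repetitions Number R of repeated splits (default 5).
#' @param balanced Balance the training split? (default TRUE)
#' @param seed Integer seed governing splits, balancing and fits.
#' @param train_fraction Training fraction per split (default 0.8).
#' @param balance_method Oversampling method for the training split.
#' @return An object of class `benchmark_result`: `runs` (one row per
#'   model x repetition) and `summary` (mean and variance of accuracy,
#'   recall, precision and F-measure per model).
#' @export
run_benchmark <- function(table, models = benchmark_factories(),
                          repetitions = 5L, balanced = TRUE, seed = 1L,
                          train_fraction = 0.8,
                          balance_method = "random_oversample") {
  stopifnot(inherits(table, "feature_table"), repetitions >= 1L)
  if (is.null(names(models)) || any(names(models) == "")) {
    stop_config("'models' must be a named list of factories")
  }
  rep_seeds <- derive_seeds(seed, repetitions * 2L)
  runs <- list()
  for (r in seq_len(repetitions)) {
    split <- stratified_split(table, train_fraction, rep_seeds[2L * r - 1L])
    train <- split$train
    if (isTRUE(balanced)) {
      train <- balance_classes(train, method = balance_method,
                               seed = rep_seeds[2L * r])
    }
    for (mname in names(models)) {
      # one seed per repetition, shared by every model: comparisons are
      # paired, so e.g. the hybrid and plain networks differ only in
      # their output layer, not in initialization or preprocessing draws
      fit_seed <- rep_seeds[2L * r]
      res <- tryCatch({
        model <- models[[mname]](train, fit_seed)
        pred <- predict(model, split$test)
        m <- evaluate_predictions(split$test$label, pred)
        cbind(data.frame(model = mname, repetition = r, error = NA_character_,
                         stringsAsFactors = FALSE),
              as.data.frame(m))
      }, error = function(e) {
        data.frame(model = mname, repetition = r,
                   error = conditionMessage(e), accuracy = NA_real_,
                   recall = NA_real_, precision = NA_real_,
                   f_measure = NA_real_, stringsAsFactors = FALSE)
      })
      runs[[length(runs) + 1L]] <- res
    }
  }
  runs <- do.call(rbind, runs)
  metric_cols <- c("accuracy", "recall", "precision", "f_measure")
  summary <- do.call(rbind, lapply(split(runs, runs$model), function(g) {
    means <- colMeans(g[metric_cols], na.rm = TRUE)
    vars <- apply(g[metric_cols], 2L, stats::var, na.rm = TRUE)
    vars[is.na(vars)] <- 0
    data.frame(model = g$model[1L],
               t(stats::setNames(means, paste0("mean_", metric_cols))),
               t(stats::setNames(vars, paste0("var_", metric_cols))),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  structure(list(runs = runs, summary = summary, balanced = balanced,
                 repetitions = repetitions, seed = seed),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> %d repetitions | training split %s\n",
              x$repetitions, if (x$balanced) "balanced" else "unbalanced"))
  print(x$summary, digits = 3)
  invisible(x)
}
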