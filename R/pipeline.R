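# End-to-end orchestration: preprocessing -> network -> feature extraction
# -> bagging ensemble, plus the prediction path that reuses all fitted
# state (never refit on test data).

# Fit every preprocessing stage on training data, in pipeline order:
# clean -> balance -> rank/select -> outlier-screen -> encode.
# Returns the fitted state plus the encoded training grids/labels.
fit_preprocessor <- function(table, config, seed) {
  seeds <- derive_seeds(seed, 4L)
  cleaned <- clean_table(table, config$cleaning)
  # pooled per-column medians of the cleaned training data, reused for
  # prediction-time imputation (class-conditional imputation needs labels)
  medians <- apply(cleaned$values, 2L, stats::median)

  balanced <- if (isTRUE(config$balance$enabled)) {
    balance_classes(cleaned, method = config$balance$method, seed = seeds[1L])
  } else {
    cleaned
  }
  ranking <- rank_feature_importance(balanced, seed = seeds[2L],
                                     n_trees = config$features$n_trees,
                                     max_depth = config$features$max_depth,
                                     min_leaf = config$features$min_leaf)
  selected <- select_features(balanced, ranking, k = config$features$k,
                              keep = config$features$keep)
  forest <- fit_isolation_forest(selected,
                                 n_trees = config$outliers$n_trees,
                                 subsample = config$outliers$subsample,
                                 seed = seeds[3L],
                                 contamination = config$outliers$contamination)
  screened <- anomaly_filter(forest, selected)
  grids <- encode_grid(screened$table)
  list(state = list(medians = medians,
                    feature_order = attr(grids, "feature_order"),
                    scaler = attr(grids, "scaler"),
                    ranking = ranking,
                    cleaning_log = cleaning_log(cleaned),
                    outlier_report = screened$removed),
       grids = grids,
       labels = screened$table$label,
       net_seed = seeds[4L])
}

# Prediction-time preprocessing: impute with stored medians, subset/order
# the selected features, standardize with the stored scaler, encode. No
# balancing, no outlier removal, no refitting.
apply_preprocessor <- function(state, table) {
  missing_cols <- setdiff(state$feature_order, colnames(table$values))
  if (length(missing_cols)) {
    stop_config("schema mismatch, missing feature columns: ",
                paste(missing_cols, collapse = ", "))
  }
  values <- table$values[, state$feature_order, drop = FALSE]
  for (j in seq_len(ncol(values))) {
    miss <- is.na(values[, j])
    if (any(miss)) {
      values[miss, j] <- state$medians[[state$feature_order[j]]]
    }
  }
  ft <- feature_table(values, ifelse(is.na(table$label), 0L, table$label))
  encode_grid(ft, scaler = state$scaler)
}

#' Train the hybrid CNN + bagging classifier
#'
#' Runs the full training pipeline: clean, balance, rank and select 36
#' features, screen outliers with an isolation forest, encode 6x6 grids,
#' train the convolutional network, extract last-dense-layer activations,
#' and fit a bagging ensemble of decision trees on them (labels mapped
#' `{0 -> -1, 1 -> +1}`). All fitted state — imputation medians, scaler
#' statistics, feature order, network weights, ensemble — is stored for the
#' prediction path, which never refits on new data.
#'
#' @param table Training [feature_table] with both classes present.
#' @param config A `run_config` (see [default_run_config()]).
#' @param seed Integer seed overriding `config$seed` (optional).
#' @return An object of class `cnnplus_model`.
#' @export
train_cnnplus <- function(table, config = default_run_config(), seed = NULL) {
  seed <- seed %||% config$seed
  pp <- fit_preprocessor(table, config, seed)
  net_cfg <- train_config(learning_rate = config$network$learning_rate,
                          max_iterations = config$network$max_iterations,
                          tolerance = config$network$tolerance,
                          batch_size = config$network$batch_size,
                          seed = pp$net_seed)
  network <- train_network(default_network_spec(), pp$grids, pp$labels,
                           net_cfg)
  feats <- extract_features(network, pp$grids)
  y_pm <- ifelse(pp$labels == 1L, 1L, -1L)
  ensemble <- fit_bagging(feats, y_pm,
                          n_learners = config$ensemble$n_learners,
                          seed = pp$net_seed + 1L,
                          max_depth = config$ensemble$max_depth,
                          min_leaf = config$ensemble$min_leaf)
  structure(list(preprocess = pp$state, network = network,
                 ensemble = ensemble, config = config, seed = seed),
            class = "cnnplus_model")
}

#' Predict with a trained hybrid model
#'
#' Applies the stored preprocessing (imputation, selection, scaling, grid
#' encoding), runs the network forward to the feature layer, and votes the
#' ensemble; vote `+1` maps back to label 1 (readmitted), `-1` to 0.
#'
#' @param object A `cnnplus_model`.
#' @param table A [feature_table] containing all selected feature columns.
#' @param ... Unused.
#' @return Integer labels in `{0, 1}`.
#' @export
predict.cnnplus_model <- function(object, table, ...) {
  grids <- apply_preprocessor(object$preprocess, table)
  feats <- extract_features(object$network, grids)
  votes <- vote_predict(object$ensemble, feats)
  as.integer(votes == 1L)
}

#' @export
print.cnnplus_model <- function(x, ...) {
  cat(sprintf("<cnnplus_model> %d selected features | %d network iterations | T = %d base learners\n",
              length(x$preprocess$feature_order), nrow(x$network$history),
              x$ensemble$n_learners))
  invisible(x)
}

#' Train the plain CNN baseline
#'
#' Same preprocessing and network as [train_cnnplus()], but classification
#' stays with the softmax output layer — the ablation the hybrid model is
#' compared against.
#'
#' @inheritParams train_cnnplus
#' @return An object of class `cnn_softmax_model`.
#' @export
train_cnn_softmax <- function(table, config = default_run_config(),
                              seed = NULL) {
  seed <- seed %||% config$seed
  pp <- fit_preprocessor(table, config, seed)
  net_cfg <- train_config(learning_rate = config$network$learning_rate,
                          max_iterations = config$network$max_iterations,
                          tolerance = config$network$tolerance,
                          batch_size = config$network$batch_size,
                          seed = pp$net_seed)
  network <- train_network(default_network_spec(), pp$grids, pp$labels,
                           net_cfg)
  structure(list(preprocess = pp$state, network = network, config = config,
                 seed = seed),
            class = "cnn_softmax_model")
}

#' @export
predict.cnn_softmax_model <- function(object, table, ...) {
  grids <- apply_preprocessor(object$preprocess, table)
  predict_softmax(object$network, grids)$labels
}
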