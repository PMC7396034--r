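#' Save a trained hybrid model
#'
#' Writes the model object as a binary archive (`model.rds`) plus a
#' human-readable JSON sidecar (`model.json`) recording the architecture
#' trace, selected features, ensemble size and configuration.
#'
#' @param model A `cnnplus_model`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
save_cnnplus_model <- function(model, dir) {
  stopifnot(inherits(model, "cnnplus_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, file.path(dir, "model.rds"))
  trace <- vapply(shape_trace(model$network$spec),
                  function(d) paste(d, collapse = "x"), character(1))
  jsonlite::write_json(
    list(package = "cnnbag",
         version = as.character(utils::packageVersion("cnnbag")),
         shape_trace = trace,
         selected_features = model$preprocess$feature_order,
         n_learners = model$ensemble$n_learners,
         seed = model$seed,
         config = unclass(model$config)),
    file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

#' Load a saved hybrid model
#'
#' @param dir Directory written by [save_cnnplus_model()].
#' @return The `cnnplus_model`.
#' @export
load_cnnplus_model <- function(dir) {
  path <- file.path(dir, "model.rds")
  if (!file.exists(path)) stop_config("no saved model at ", dir)
  model <- readRDS(path)
  stopifnot(inherits(model, "cnnplus_model"))
  model
}
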