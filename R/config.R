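#' Default run configuration
#'
#' All tunable knobs of the pipeline, with their defaults: cleaning policy,
#' balancing method, feature selection size (36, one full 6x6 grid),
#' isolation-forest settings, network training settings, ensemble size and
#' benchmark protocol. [load_config()] merges a user file over these
#' defaults and rejects unknown keys.
#'
#' @return A nested named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    label_column = "label",
    missing_tokens = c("NA", ""),
    cleaning = list(max_missing_frac = 0.5),
    balance = list(enabled = TRUE, method = "smote"),
    features = list(k = 36L, n_trees = 20L, max_depth = 8L, min_leaf = 5L,
                    keep = character(0)),
    outliers = list(n_trees = 100L, subsample = 256L, contamination = 0.05),
    network = list(learning_rate = 1e-4, max_iterations = 200L,
                   tolerance = 1e-6, batch_size = 256L),
    ensemble = list(n_learners = 21L, max_depth = 8L, min_leaf = 5L),
    benchmark = list(repetitions = 5L, train_fraction = 0.8, balanced = TRUE),
    seed = 1L), class = "run_config")
}

merge_config <- function(defaults, override, path = character(0)) {
  for (key in names(override)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults)) {
      stop_config("unknown config key '", full, "'; valid keys here: ",
                  paste(names(defaults), collapse = ", "))
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(override[[key]])) {
        stop_config("config key '", full, "' must be a mapping")
      }
      defaults[[key]] <- merge_config(defaults[[key]], override[[key]],
                                      c(path, key))
    } else {
      defaults[[key]] <- override[[key]]
    }
  }
  defaults
}

#' Load a run configuration file
#'
#' Reads a YAML or JSON configuration, fills unset fields from
#' [default_run_config()], and rejects unknown keys (listing the valid ones).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file; `NULL` returns the
#'   defaults.
#' @return A fully resolved `run_config`.
#' @export
load_config <- function(path = NULL) {
  defaults <- default_run_config()
  if (is.null(path)) return(defaults)
  if (!file.exists(path)) stop_config("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) return(defaults)
  structure(merge_config(unclass(defaults), raw), class = "run_config")
}

#' Write a reproducibility manifest
#'
#' Records the fully resolved configuration, the top-level seed and the
#' package version — enough to reproduce a run bit for bit.
#'
#' @param config A `run_config`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(config, path) {
  jsonlite::write_json(
    list(package = "cnnbag",
         version = as.character(utils::packageVersion("cnnbag")),
         config = unclass(config)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
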