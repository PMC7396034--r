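#' Encode a 36-feature table as 6x6 single-channel grids
#'
#' Standardizes each feature to zero mean / unit variance (statistics
#' computed from this table, or reused from a previous encoding via
#' `scaler`, so prediction-time data is scaled with training statistics)
#' and places the features row-major into a 6x6 grid: grid cell (r, c)
#' holds the feature at column position `6 * (r - 1) + c`. Since
#' [select_features()] orders columns by descending importance, the most
#' important feature lands in the top-left cell. Zero-variance columns are
#' encoded as all zeros with a warning.
#'
#' @param table A [feature_table] with exactly 36 feature columns and no
#'   missing cells.
#' @param scaler Optional list with `mean` and `sd` (named numeric vectors)
#'   from a previous call; if `NULL`, computed from `table`.
#' @return A `grid_batch`: an n x 6 x 6 x 1 array with attributes
#'   `feature_order` (the 36 column names, row-major) and `scaler`.
#' @seealso [decode_grid()] for the exact inverse mapping.
#' @export
encode_grid <- function(table, scaler = NULL) {
  stopifnot(inherits(table, "feature_table"))
  h <- 6L; w <- 6L
  if (n_features(table) != h * w) {
    stop_config("grid encoding requires exactly ", h * w, " feature columns, got ",
                n_features(table))
  }
  if (anyNA(table$values)) stop_config("grid encoding requires no missing cells")
  x <- table$values
  if (is.null(scaler)) {
    scaler <- list(mean = colMeans(x), sd = apply(x, 2L, stats::sd))
    if (any(scaler$sd == 0)) {
      warning("zero-variance column(s) encoded as zeros: ",
              paste(colnames(x)[scaler$sd == 0], collapse = ", "))
    }
  } else {
    if (!identical(names(scaler$mean), colnames(x))) {
      stop_config("scaler does not match the table's columns")
    }
  }
  sd_safe <- ifelse(scaler$sd == 0, 1, scaler$sd)
  z <- sweep(sweep(x, 2L, scaler$mean, "-"), 2L, sd_safe, "/")
  z[, scaler$sd == 0] <- 0

  n <- nrow(z)
  grids <- array(0, dim = c(n, h, w, 1L))
  for (r in seq_len(h)) {
    for (cc in seq_len(w)) {
      grids[, r, cc, 1L] <- z[, w * (r - 1L) + cc]
    }
  }
  structure(grids, feature_order = colnames(x), scaler = scaler,
            class = "grid_batch")
}

#' Decode grids back to the standardized feature matrix
#'
#' Exact inverse of the [encode_grid()] cell mapping (values stay on the
#' standardized scale).
#'
#' @param grids A `grid_batch`.
#' @return Numeric matrix n x 36 with the original column names.
#' @export
decode_grid <- function(grids) {
  stopifnot(inherits(grids, "grid_batch"))
  d <- dim(grids)
  h <- d[2L]; w <- d[3L]
  out <- matrix(0, d[1L], h * w)
  for (r in seq_len(h)) {
    for (cc in seq_len(w)) {
      out[, w * (r - 1L) + cc] <- grids[, r, cc, 1L]
    }
  }
  colnames(out) <- attr(grids, "feature_order")
  out
}

# Convert a grid_batch (n, H, W, C) to the network's channel-first input
# layout: a (C, H, W, n) array, memory-identical to a (C*H*W) x n matrix.
grid_to_input <- function(grids) {
  aperm(unclass(grids), c(4L, 2L, 3L, 1L))
}
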