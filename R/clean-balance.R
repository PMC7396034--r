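#' Clean a feature table
#'
#' First preprocessing stage: resolves missing values. Rows with a missing
#' label, or with more than `max_missing_frac` of their feature cells missing,
#' are dropped; every remaining missing cell is imputed by the
#' class-conditional median of its column (falling back to the pooled median
#' when a class has no observed value, and to 0 for an entirely missing
#' column, with a warning).
#'
#' @param table A [feature_table] with at least one row.
#' @param policy List of cleaning options; currently `max_missing_frac`
#'   (default 0.5), the per-row missing fraction above which a row is dropped.
#' @return A [feature_table] with no missing markers and an attribute
#'   `cleaning_log` (counts per rule), retrievable with [cleaning_log()].
#' @export
clean_table <- function(table, policy = list(max_missing_frac = 0.5)) {
  stopifnot(inherits(table, "feature_table"))
  if (n_rows(table) < 1L) stop_config("clean_table requires at least one row")
  max_frac <- policy$max_missing_frac %||% 0.5

  drop_label <- is.na(table$label)
  frac_missing <- rowMeans(is.na(table$values))
  drop_frac <- !drop_label & frac_missing > max_frac
  keep <- !(drop_label | drop_frac)
  if (!any(keep)) stop_config("cleaning dropped every row (empty output)")

  values <- table$values[keep, , drop = FALSE]
  label <- table$label[keep]
  n_imputed <- 0L
  for (j in seq_len(ncol(values))) {
    miss <- is.na(values[, j])
    if (!any(miss)) next
    pooled <- stats::median(values[, j], na.rm = TRUE)
    for (cls in c(0L, 1L)) {
      rows <- miss & label == cls
      if (!any(rows)) next
      med <- stats::median(values[label == cls, j], na.rm = TRUE)
      if (is.na(med)) med <- pooled
      if (is.na(med)) {
        warning("column '", colnames(values)[j],
                "' has no observed values; imputing 0")
        med <- 0
      }
      values[rows, j] <- med
    }
    n_imputed <- n_imputed + sum(miss)
  }

  out <- feature_table(values, label)
  attr(out, "cleaning_log") <- list(
    dropped_missing_label = sum(drop_label),
    dropped_missing_fraction = sum(drop_frac),
    imputed_cells = n_imputed)
  out
}

#' @rdname clean_table
#' @param x A cleaned [feature_table].
#' @export
cleaning_log <- function(x) attr(x, "cleaning_log")

#' Balance class counts by oversampling
#'
#' Equalizes the two class counts by growing the minority class up to the
#' majority count. All original rows are preserved, in order, at the top of
#' the output. `"random_oversample"` replicates minority rows drawn with
#' replacement; `"smote"` synthesizes new minority rows as
#' `x_i + lambda * (x_nn - x_i)` with `lambda ~ U(0, 1)` and `x_nn` one of
#' the `k = 5` nearest minority neighbours of `x_i`.
#'
#' @param table A [feature_table] with both classes present.
#' @param method `"random_oversample"` or `"smote"`.
#' @param seed Integer seed; output is deterministic per seed.
#' @param k Number of nearest neighbours for SMOTE (default 5, capped at
#'   the minority count minus one).
#' @return A [feature_table] with exactly equal class counts. An
#'   already-balanced table is returned unchanged.
#' @export
balance_classes <- function(table, method = c("random_oversample", "smote"),
                            seed = 1L, k = 5L) {
  stopifnot(inherits(table, "feature_table"))
  method <- match.arg(method)
  counts <- c(sum(table$label == 0L), sum(table$label == 1L))
  if (any(counts == 0L)) {
    stop_config("degenerate labels: only one class present")
  }
  if (counts[1L] == counts[2L]) return(table)
  minority <- if (counts[1L] < counts[2L]) 0L else 1L
  n_needed <- abs(counts[1L] - counts[2L])
  min_idx <- which(table$label == minority)

  new_rows <- with_seed(seed, {
    if (method == "random_oversample") {
      table$values[sample(min_idx, n_needed, replace = TRUE), , drop = FALSE]
    } else {
      if (length(min_idx) < 2L) {
        stop_config("smote requires at least 2 minority rows (insufficient neighbours)")
      }
      xm <- table$values[min_idx, , drop = FALSE]
      if (anyNA(xm)) stop_config("smote requires a cleaned table (no missing cells)")
      k_use <- min(k, nrow(xm) - 1L)
      d <- as.matrix(stats::dist(xm))
      diag(d) <- Inf
      nn_raw <- apply(d, 1L, function(r) order(r)[seq_len(k_use)])
      nn <- if (k_use == 1L) cbind(nn_raw) else t(nn_raw)
      base <- sample.int(nrow(xm), n_needed, replace = TRUE)
      lam <- stats::runif(n_needed)
      pick <- nn[cbind(base, sample.int(k_use, n_needed, replace = TRUE))]
      xm[base, , drop = FALSE] +
        lam * (xm[pick, , drop = FALSE] - xm[base, , drop = FALSE])
    }
  })
  feature_table(rbind(table$values, new_rows),
                c(table$label, rep(minority, n_needed)))
}
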