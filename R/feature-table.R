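#' Construct a feature table
#'
#' The tabular currency of the package: an n x p numeric matrix of named
#' features (with `NA` as the explicit missing marker) plus a binary label
#' vector. All preprocessing stages consume and return this container.
#'
#' @param values Numeric matrix (rows are encounters, columns are features).
#' @param label Vector of labels in `{0, 1}` (`NA` allowed before cleaning),
#'   one per row.
#' @param column_names Optional character vector of unique feature names;
#'   defaults to `colnames(values)`.
#' @return An object of class `feature_table` with elements `values`
#'   (named numeric matrix) and `label` (integer vector).
#' @examples
#' ft <- feature_table(matrix(rnorm(20), 10, 2,
#'                            dimnames = list(NULL, c("age", "bmi"))),
#'                     label = rep(c(0, 1), 5))
#' n_rows(ft)
#' @export
feature_table <- function(values, label, column_names = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(column_names)) {
    column_names <- sprintf("x%02d", seq_len(ncol(values)))
  }
  if (length(column_names) != ncol(values)) {
    stop_config("column_names length must match the number of feature columns")
  }
  if (anyDuplicated(column_names)) {
    dup <- unique(column_names[duplicated(column_names)])
    stop_config("duplicate feature names: ", paste(dup, collapse = ", "))
  }
  colnames(values) <- column_names
  if (length(label) != nrow(values)) {
    stop_config("label length (", length(label), ") must equal row count (",
                nrow(values), ")")
  }
  bad <- !is.na(label) & !(label %in% c(0, 1))
  if (any(bad)) {
    stop_config("non-binary label values at rows: ",
                paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  structure(list(values = values, label = as.integer(label)),
            class = "feature_table")
}

#' @rdname feature_table
#' @param x A `feature_table`.
#' @export
n_rows <- function(x) nrow(x$values)

#' @rdname feature_table
#' @export
n_features <- function(x) ncol(x$values)

#' @export
print.feature_table <- function(x, ...) {
  cts <- table(factor(x$label, levels = c(0, 1)))
  cat(sprintf("<feature_table> %d rows x %d features | labels 0:%d 1:%d | %d missing cells\n",
              n_rows(x), n_features(x), cts[["0"]], cts[["1"]],
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
as.data.frame.feature_table <- function(x, ...) {
  out <- as.data.frame(x$values)
  out$label <- x$label
  out
}

# Subset rows of a feature table, preserving class and column order.
ft_rows <- function(x, idx) {
  feature_table(x$values[idx, , drop = FALSE], x$label[idx])
}

# Subset/reorder columns by name.
ft_cols <- function(x, cols) {
  missing <- setdiff(cols, colnames(x$values))
  if (length(missing)) {
    stop_config("schema mismatch, missing feature columns: ",
                paste(missing, collapse = ", "))
  }
  feature_table(x$values[, cols, drop = FALSE], x$label)
}
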