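#' Read a feature table from CSV
#'
#' Parses a delimited text file (comma-separated, header mandatory) into a
#' [feature_table]. Cells matching one of `missing_tokens` become explicit
#' `NA` markers; any other cell that fails numeric parsing is reported with
#' its row/column coordinates.
#'
#' @param path Path to a CSV file with a header row.
#' @param label_column Name of the binary label column (default `"label"`).
#' @param missing_tokens Character vector of tokens read as missing
#'   (default `c("NA", "")`).
#' @return A [feature_table].
#' @export
read_feature_table <- function(path, label_column = "label",
                               missing_tokens = c("NA", "")) {
  if (!file.exists(path)) stop_config("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = NULL)
  if (!nrow(raw)) stop_config("empty table in ", path)
  if (anyDuplicated(names(raw))) {
    stop_config("duplicate columns in ", path, ": ",
                paste(unique(names(raw)[duplicated(names(raw))]), collapse = ", "))
  }
  if (!label_column %in% names(raw)) {
    stop_config("label column '", label_column, "' not found in ", path)
  }
  parse_col <- function(txt, col) {
    txt[txt %in% missing_tokens] <- NA_character_
    num <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(num) & !is.na(txt))
    if (length(bad)) {
      stop_config(sprintf("unparseable cell at row %d, column '%s': '%s'",
                          bad[1L], col, txt[bad[1L]]))
    }
    num
  }
  label <- parse_col(raw[[label_column]], label_column)
  bad_lab <- which(!is.na(label) & !(label %in% c(0, 1)))
  if (length(bad_lab)) {
    stop_config(sprintf("non-binary label value %s at row %d",
                        format(label[bad_lab[1L]]), bad_lab[1L]))
  }
  feat_cols <- setdiff(names(raw), label_column)
  values <- vapply(feat_cols, function(cl) parse_col(raw[[cl]], cl),
                   numeric(nrow(raw)))
  if (is.null(dim(values))) values <- matrix(values, nrow = 1L)
  colnames(values) <- feat_cols
  feature_table(values, label)
}

#' Write a feature table to CSV
#'
#' @param table A [feature_table].
#' @param path Output path; missing cells are written as `NA`.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "NA")
  invisible(path)
}
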