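#' Confusion-matrix classification metrics
#'
#' Computes accuracy `(TP + TN) / (P + N)`, recall `TP / P`, precision
#' `TP / (TP + FP)` and F-measure `2TP / (2TP + FP + FN)` with class 1 as
#' the positive class and `P`, `N` the counts of actual positives and
#' negatives. A metric whose denominator is zero is reported as 0 with a
#' warning. In the clinical readmission setting recall is the headline
#' number: it bounds how often a high-risk patient is missed.
#'
#' @param truth Actual labels in `{0, 1}`.
#' @param predicted Predicted labels in `{0, 1}`, same length.
#' @return An object of class `metrics_report`: `accuracy`, `recall`,
#'   `precision`, `f_measure`, and counts `tp`, `tn`, `fp`, `fn`.
#' @examples
#' evaluate_predictions(c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0),
#'                      c(1, 1, 1, 0, 1, 1, 0, 0, 0, 0))
#' @export
evaluate_predictions <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop_config("truth and predicted have different lengths")
  }
  if (!all(truth %in% c(0, 1)) || !all(predicted %in% c(0, 1))) {
    stop_config("labels must be in {0, 1}")
  }
  tp <- sum(truth == 1 & predicted == 1)
  tn <- sum(truth == 0 & predicted == 0)
  fp <- sum(truth == 0 & predicted == 1)
  fn <- sum(truth == 1 & predicted == 0)
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reported as 0")
      0
    } else {
      num / den
    }
  }
  structure(list(accuracy = (tp + tn) / length(truth),
                 recall = ratio(tp, tp + fn, "recall"),
                 precision = ratio(tp, tp + fp, "precision"),
                 f_measure = ratio(2 * tp, 2 * tp + fp + fn, "F-measure"),
                 tp = tp, tn = tn, fp = fp, fn = fn),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.3f | recall %.3f | precision %.3f | F-measure %.3f (TP %d FP %d FN %d TN %d)\n",
              x$accuracy, x$recall, x$precision, x$f_measure,
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(accuracy = x$accuracy, recall = x$recall,
             precision = x$precision, f_measure = x$f_measure)
}
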