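#' Confusion counts for binary binder/non-binder calls
#'
#' TP counts binders (actual 1) predicted as binders, TN non-binders
#' predicted as non-binders, FN binders predicted as non-binders, FP
#' non-binders predicted as binders.
#'
#' @param actual,predicted equal-length vectors of 0/1 values.
#' @return A list of class `confusion_counts` with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(actual, predicted) {
  if (length(actual) != length(predicted))
    stop("actual and predicted have different lengths")
  if (!all(actual %in% c(0, 1)) || !all(predicted %in% c(0, 1)))
    stop("labels and calls must be 0 or 1")
  structure(list(tp = sum(actual == 1 & predicted == 1),
                 tn = sum(actual == 0 & predicted == 0),
                 fp = sum(actual == 0 & predicted == 1),
                 fn = sum(actual == 1 & predicted == 0)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("confusion: TP =", x$tp, " TN =", x$tn, " FP =", x$fp, " FN =", x$fn,
      "\n")
  invisible(x)
}

#' Classification performance metrics
#'
#' Computes the five standard QSAR classification metrics from a confusion
#' table:
#' accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, and balanced
#' accuracy, the mean of sensitivity and specificity.
#'
#' Conventions for degenerate tables: MCC is 0 when any denominator factor is
#' zero; sensitivity (resp. specificity) is `NA` when there are no actual
#' positives (negatives), and balanced accuracy is `NA` whenever either is —
#' reporting an undefined rate as 0 would silently distort aggregates.
#'
#' @param cc a [confusion_counts()] object (or list with `tp`, `tn`, `fp`,
#'   `fn`), with at least one counted chemical.
#' @return A list of class `metric_report` with elements `accuracy`,
#'   `sensitivity`, `specificity`, `mcc`, `balanced_accuracy`.
#' @export
classification_metrics <- function(cc) {
  tp <- cc$tp; tn <- cc$tn; fp <- cc$fp; fn <- cc$fn
  total <- tp + tn + fp + fn
  if (total < 1) stop("empty confusion table")
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else 0
  structure(list(accuracy = (tp + tn) / total,
                 sensitivity = sens,
                 specificity = spec,
                 mcc = mcc,
                 balanced_accuracy = (sens + spec) / 2),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, digits = 3, ...) {
  v <- unlist(x)
  cat(paste(format(names(v), width = 18), round(v, digits)), sep = "\n")
  invisible(x)
}

#' @rdname classification_metrics
#' @param actual,predicted 0/1 vectors; shorthand for
#'   `classification_metrics(confusion_counts(actual, predicted))`.
#' @export
score_predictions <- function(actual, predicted) {
  classification_metrics(confusion_counts(actual, predicted))
}
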