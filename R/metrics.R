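#' Confusion counts from truth/prediction label vectors
#'
#' @param truth,prediction Character vectors of \code{"positive"} /
#'   \code{"negative"} labels, equal length.
#' @return A list of class \code{hp_confusion} with fields \code{tp},
#'   \code{tn}, \code{fp}, \code{fn}.
#' @export
confusion_counts <- function(truth, prediction) {
  stopifnot(length(truth) == length(prediction),
            all(truth %in% c("positive", "negative")),
            all(prediction %in% c("positive", "negative")))
  cc <- list(tp = sum(truth == "positive" & prediction == "positive"),
             tn = sum(truth == "negative" & prediction == "negative"),
             fp = sum(truth == "negative" & prediction == "positive"),
             fn = sum(truth == "positive" & prediction == "negative"))
  class(cc) <- "hp_confusion"
  cc
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Confusion-matrix performance metrics
#'
#' Computes accuracy, sensitivity (recall), specificity, precision, F1 and
#' the Matthews correlation coefficient from a confusion table. MCC uses the
#' standard square-rooted denominator
#' \eqn{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}, which bounds it in \[-1, 1\];
#' \code{mcc_sqrt = FALSE} gives the unrooted variant for audit. Any metric
#' with a zero denominator is reported as \code{NA}, never silently zeroed.
#'
#' @param counts An [confusion_counts()] object (or list with tp/tn/fp/fn).
#' @param mcc_sqrt Use the square-rooted MCC denominator. Default TRUE.
#' @return A list of class \code{hp_metrics}.
#' @export
#' @examples
#' m <- compute_metrics(confusion_counts(
#'   c("positive", "positive", "negative"),
#'   c("positive", "negative", "negative")))
#' m$accuracy
compute_metrics <- function(counts, mcc_sqrt = TRUE) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  n <- tp + tn + fp + fn
  if (n == 0) stop("no evaluated rows: all confusion counts are zero",
                   call. = FALSE)
  precision <- safe_ratio(tp, tp + fp)
  recall <- safe_ratio(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  mcc_den <- prod(c(tp + fp, tp + fn, tn + fp, tn + fn))
  mcc <- if (mcc_den == 0) {
    NA_real_
  } else if (mcc_sqrt) {
    (tp * tn - fp * fn) / sqrt(mcc_den)
  } else {
    (tp * tn - fp * fn) / mcc_den
  }
  out <- list(accuracy = (tp + tn) / n,
              sensitivity = recall,
              specificity = safe_ratio(tn, tn + fp),
              precision = precision,
              f1 = f1,
              mcc = mcc,
              counts = counts)
  class(out) <- "hp_metrics"
  out
}

#' @export
print.hp_metrics <- function(x, ...) {
  cat(sprintf(
    "accuracy %.4f | sens %.4f | spec %.4f | prec %.4f | F1 %.4f | MCC %.4f\n",
    x$accuracy, x$sensitivity, x$specificity, x$precision, x$f1, x$mcc))
  invisible(x)
}
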