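#' Confusion counts at a probability threshold
#'
#' The stressed condition is the positive class; a segment is called
#' positive when its predicted probability is at least the threshold.
#'
#' @param y_true Binary labels (1 = stressed).
#' @param y_prob Predicted probabilities, same length.
#' @param threshold Decision threshold.
#' @return An object of class `confusion_counts` with integer fields `TP`,
#'   `FP`, `FN`, `TN` summing to `length(y_true)`.
#' @export
confusion_counts <- function(y_true, y_prob, threshold = 0.5) {
  if (!length(y_true)) stop("empty input", call. = FALSE)
  if (length(y_true) != length(y_prob)) {
    stop("`y_true` and `y_prob` must have equal length", call. = FALSE)
  }
  if (!all(y_true %in% c(0, 1))) {
    stop("`y_true` must be binary (0/1)", call. = FALSE)
  }
  pred <- as.integer(y_prob >= threshold)
  structure(
    list(TP = sum(pred == 1 & y_true == 1),
         FP = sum(pred == 1 & y_true == 0),
         FN = sum(pred == 0 & y_true == 1),
         TN = sum(pred == 0 & y_true == 0)),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts>  (rows: truth, cols: prediction)\n")
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2,
              dimnames = list(c("stressed", "non_stressed"),
                              c("pred_stressed", "pred_non_stressed")))
  print(m)
  invisible(x)
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' The four standard binary-classification metrics, reported in percent:
#' accuracy `(TP+TN)/(TP+FP+FN+TN)`, precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)` and F1 `TP/(TP + (FP+FN)/2)` (the harmonic mean of
#' precision and recall).  A metric whose denominator is zero is undefined
#' and reported as `NA` with a warning, never as 0.
#'
#' @param counts A [confusion_counts()] object.
#' @return Named numeric vector `accuracy`, `precision`, `recall`, `f1`, in
#'   percent.
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  n <- counts$TP + counts$FP + counts$FN + counts$TN
  if (n == 0) stop("no samples", call. = FALSE)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s is undefined (zero denominator)", what))
      return(NA_real_)
    }
    num / den
  }
  accuracy <- (counts$TP + counts$TN) / n
  precision <- safe_div(counts$TP, counts$TP + counts$FP, "precision")
  recall <- safe_div(counts$TP, counts$TP + counts$FN, "recall")
  f1 <- safe_div(counts$TP, counts$TP + (counts$FP + counts$FN) / 2, "F1")
  100 * c(accuracy = accuracy, precision = precision, recall = recall,
          f1 = f1)
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique predicted probabilities (descending),
#' yielding the standard step ROC from (0, 0) to (1, 1); the AUC is the
#' trapezoidal integral of that curve, which for a step ROC equals the
#' Mann–Whitney rank statistic (ties counted half).
#'
#' @param y_true Binary labels (1 = stressed); both classes must be present.
#' @param y_prob Predicted probabilities.
#' @return A list of class `roc_curve` with `roc` (data frame of
#'   `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(y_true, y_prob) {
  if (length(y_true) != length(y_prob)) {
    stop("`y_true` and `y_prob` must have equal length", call. = FALSE)
  }
  n_pos <- sum(y_true == 1)
  n_neg <- sum(y_true == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present for a ROC curve", call. = FALSE)
  }
  thr <- sort(unique(y_prob), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(y_prob >= t & y_true == 1) / n_pos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(y_prob >= t & y_true == 0) / n_neg,
                numeric(1))
  roc <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                    tpr = c(0, tpr))
  if (roc$fpr[nrow(roc)] != 1 || roc$tpr[nrow(roc)] != 1) {
    roc <- rbind(roc, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  }
  auc <- sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
  structure(list(roc = roc, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, AUC = %.4f\n", nrow(x$roc), x$auc))
  invisible(x)
}

#' Full evaluation report
#'
#' Confusion counts, the four percentage metrics, and the ROC/AUC in one
#' object.
#'
#' @param y_true Binary labels (1 = stressed).
#' @param y_prob Predicted probabilities.
#' @param threshold Decision threshold for the confusion matrix.
#' @return An object of class `eval_report` with `counts`, `accuracy`,
#'   `precision`, `recall`, `f1` (percent), `roc` (data frame) and `auc`.
#' @export
eval_report <- function(y_true, y_prob, threshold = 0.5) {
  counts <- confusion_counts(y_true, y_prob, threshold)
  metrics <- classification_metrics(counts)
  roc <- roc_auc(y_true, y_prob)
  structure(
    list(counts = counts,
         accuracy = unname(metrics["accuracy"]),
         precision = unname(metrics["precision"]),
         recall = unname(metrics["recall"]),
         f1 = unname(metrics["f1"]),
         roc = roc$roc,
         auc = roc$auc,
         threshold = threshold,
         n = length(y_true)),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> n = %d\n  accuracy %.2f%%  precision %.2f%%  recall %.2f%%  F1 %.2f%%  AUC %.3f\n",
    x$n, x$accuracy, x$precision, x$recall, x$f1, x$auc))
  invisible(x)
}

eval_report_as_list <- function(report) {
  list(
    n = report$n,
    threshold = report$threshold,
    counts = report$counts[c("TP", "FP", "FN", "TN")],
    accuracy = round(report$accuracy, 2),
    precision = round(report$precision, 2),
    recall = round(report$recall, 2),
    f1 = round(report$f1, 2),
    auc = report$auc
  )
}
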