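# Binary-classification metric suite: thresholded confusion-matrix summaries
# (accuracy, sensitivity, specificity, precision, MCC), rank-statistic AUC
# with ties credited 0.5, and step-wise (non-interpolated) area under the
# precision-recall curve, plus the ROC/PR curve points themselves.

#' Classification metrics for scored pairs
#'
#' Thresholded metrics use the confusion matrix at `threshold`; AUC is the
#' probability that a random positive outscores a random negative (ties
#' credited 0.5, i.e. the midrank statistic), identical to the trapezoidal
#' area under the ROC curve with tied scores grouped. AUPR is the step-wise
#' sum of precision times recall increments at each distinct score.
#'
#' @param labels 0/1 vector; both classes must be present.
#' @param scores finite numeric scores, higher = more likely positive.
#' @param threshold score threshold for the confusion matrix.
#' @return list of class `mda_metrics`: `acc`, `sen`, `spec`, `prec`, `mcc`,
#'   `auc`, `aupr`, `threshold`, `confusion` (tp/fp/tn/fn), `roc_points`
#'   (data.frame fpr/tpr), `pr_points` (data.frame recall/precision).
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores)) stop("labels/scores length mismatch")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (any(!is.finite(scores))) stop("scores must be finite")
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) {
    stop("both classes must be present (AUC undefined otherwise)")
  }

  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  acc <- (tp + tn) / length(labels)
  sen <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  prec <- if (tp + fp == 0L) NA_real_ else tp / (tp + fp)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den

  r <- rank(scores)                         # midranks handle ties
  auc <- (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)

  curves <- score_curves(labels, scores, np, nn)

  structure(list(acc = acc, sen = sen, spec = spec, prec = prec, mcc = mcc,
                 auc = auc, aupr = curves$aupr, threshold = threshold,
                 confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
                 roc_points = curves$roc, pr_points = curves$pr),
            class = "mda_metrics")
}

# ROC/PR points over distinct-score prefixes (ties grouped), plus the
# step-wise AUPR (sum of precision * recall increments).
score_curves <- function(labels, scores, np, nn) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  last <- cumsum(rle(s)$lengths)            # end of each tie group
  tp <- cumsum(y)[last]
  fp <- last - tp
  roc <- data.frame(fpr = c(0, fp / nn), tpr = c(0, tp / np))
  recall <- tp / np
  precision <- tp / (tp + fp)
  aupr <- sum(diff(c(0, recall)) * precision)
  pr <- data.frame(recall = c(0, recall),
                   precision = c(precision[1L], precision))
  list(roc = roc, pr = pr, aupr = aupr)
}

#' Trapezoidal area under a curve given as points
#' @param x,y coordinates in plotting order.
#' @return the trapezoidal integral of `y` over `x`.
#' @export
trapezoid_area <- function(x, y) {
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' @export
print.mda_metrics <- function(x, ...) {
  cat(sprintf(
    "Acc %.4f | Sen %.4f | Spec %.4f | Prec %s | MCC %.4f | AUC %.4f | AUPR %.4f\n",
    x$acc, x$sen, x$spec,
    if (is.na(x$prec)) "NA" else sprintf("%.4f", x$prec),
    x$mcc, x$auc, x$aupr))
  invisible(x)
}
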