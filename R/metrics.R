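## Evaluation metrics for the three-class disposal classifier. All curves
## are computed from class scores by explicit threshold sweeps and
## trapezoidal integration, so they can be cross-checked against an
## independent implementation.

#' Confusion matrix
#'
#' @param truth,predicted Factors (or vectors coercible to factors) over the
#'   same set of class levels.
#' @param levels Class levels fixing row/column order; defaults to the union
#'   of levels of `truth`.
#' @return Integer matrix, rows = true class, columns = predicted class.
#' @export
confusion_matrix <- function(truth, predicted, levels = NULL) {
  if (is.null(levels)) levels <- base::levels(factor(truth))
  truth <- factor(truth, levels = levels)
  predicted <- factor(predicted, levels = levels)
  as.matrix(table(truth = truth, predicted = predicted))
}

#' Per-class precision, recall and F1 from a confusion matrix
#'
#' Precision is true positives over predicted positives, recall true
#' positives over actual positives, F1 their harmonic mean. A class with no
#' predicted positives gets precision 0 (and F1 0); a class absent from the
#' truth gets recall `NA` and its metrics are flagged undefined.
#'
#' @param cm Confusion matrix (rows = truth, columns = predicted).
#' @return Data frame `class`, `precision`, `recall`, `f1`, `support`.
#' @export
precision_recall_f1 <- function(cm) {
  classes <- rownames(cm)
  tp <- diag(cm)
  pred_pos <- colSums(cm)
  actual_pos <- rowSums(cm)
  precision <- ifelse(pred_pos > 0, tp / pred_pos, 0)
  recall <- ifelse(actual_pos > 0, tp / actual_pos, NA_real_)
  f1 <- ifelse(!is.na(recall) & (precision + recall) > 0,
    2 * precision * recall / (precision + recall), ifelse(is.na(recall), NA, 0)
  )
  data.frame(
    class = classes, precision = unname(precision), recall = unname(recall),
    f1 = unname(f1), support = unname(actual_pos), stringsAsFactors = FALSE
  )
}

#' Macro-averaged F1
#'
#' Mean of the per-class F1 scores over the classes present in the truth.
#'
#' @param truth,predicted Class vectors.
#' @param levels Optional fixed class levels.
#' @return Scalar macro-F1.
#' @export
macro_f1 <- function(truth, predicted, levels = NULL) {
  m <- precision_recall_f1(confusion_matrix(truth, predicted, levels))
  mean(m$f1, na.rm = TRUE)
}

## ROC points from binary truth and scores (higher score = positive);
## returns fpr/tpr stepping through distinct thresholds, tie-grouped.
.roc_points <- function(truth, score) {
  o <- order(score, decreasing = TRUE)
  truth <- truth[o]
  score <- score[o]
  P <- sum(truth)
  N <- sum(!truth)
  tp <- cumsum(truth)
  fp <- cumsum(!truth)
  last_of_tie <- c(score[-1] != score[-length(score)], TRUE)
  tpr <- c(0, tp[last_of_tie] / max(P, 1))
  fpr <- c(0, fp[last_of_tie] / max(N, 1))
  data.frame(fpr = fpr, tpr = tpr)
}

.trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))

#' One-vs-all ROC-AUC
#'
#' Area under the ROC curve of the binary problem "class vs rest", by
#' trapezoidal integration over the threshold sweep of the class scores.
#'
#' @param truth Logical vector (TRUE = positive class) or class vector with
#'   `positive` naming the positive class.
#' @param score Numeric scores, higher meaning more positive.
#' @param positive Positive class label when `truth` is not logical.
#' @return AUC in `[0, 1]`; `NA` if either class is absent.
#' @export
roc_auc <- function(truth, score, positive = NULL) {
  if (!is.logical(truth)) truth <- truth == positive
  if (!any(truth) || all(truth)) return(NA_real_)
  p <- .roc_points(truth, score)
  .trapz(p$fpr, p$tpr)
}

## Precision-recall points through the threshold sweep.
.pr_points <- function(truth, score) {
  o <- order(score, decreasing = TRUE)
  truth <- truth[o]
  score <- score[o]
  P <- sum(truth)
  tp <- cumsum(truth)
  k <- seq_along(truth)
  last_of_tie <- c(score[-1] != score[-length(score)], TRUE)
  recall <- tp[last_of_tie] / max(P, 1)
  precision <- (tp / k)[last_of_tie]
  data.frame(
    recall = c(0, recall),
    precision = c(precision[1], precision)
  )
}

#' One-vs-all PR-AUC
#'
#' Area under the precision-recall curve by trapezoidal integration over
#' recall.
#'
#' @inheritParams roc_auc
#' @return AUC in `[0, 1]`; `NA` if the positive class is absent.
#' @export
pr_auc <- function(truth, score, positive = NULL) {
  if (!is.logical(truth)) truth <- truth == positive
  if (!any(truth)) return(NA_real_)
  p <- .pr_points(truth, score)
  .trapz(p$recall, p$precision)
}

#' Micro-average ROC curve and AUC
#'
#' Pools every one-vs-all decision (one per sample per class) into a single
#' binary problem and computes its ROC curve; this is the overall-performance
#' curve conventionally reported for multi-class classifiers.
#'
#' @param truth Factor of true classes.
#' @param scores Matrix of class scores, one column per class (column names
#'   must be the class levels).
#' @return List with `points` (data frame `fpr`, `tpr`) and `auc`.
#' @export
micro_roc <- function(truth, scores) {
  levels <- colnames(scores)
  truth <- factor(truth, levels = levels)
  bin <- as.vector(vapply(levels, function(l) truth == l, logical(length(truth))))
  sc <- as.vector(scores)
  pts <- .roc_points(bin, sc)
  list(points = pts, auc = .trapz(pts$fpr, pts$tpr))
}
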