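# Binary-classification evaluation: confusion counts, the five standard
# metrics, and the rank-statistic AUROC.

#' Confusion counts at a score threshold
#'
#' @param scores numeric prediction scores (P(positive)).
#' @param labels 0/1 true labels aligned to `scores`.
#' @param threshold classification threshold (default 0.5).
#' @return A list with integer fields `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  pred <- as.integer(scores >= threshold)
  list(TP = sum(pred == 1 & labels == 1),
       TN = sum(pred == 0 & labels == 0),
       FP = sum(pred == 1 & labels == 0),
       FN = sum(pred == 0 & labels == 1))
}

#' Area under the ROC curve (rank statistic)
#'
#' Computed as the probability that a random positive outscores a random
#' negative, with ties credited one half — equivalent to trapezoidal
#' integration of the empirical ROC curve.
#'
#' @inheritParams confusion_counts
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  if (np == 0 || nn == 0) stop("AUROC undefined: both classes required")
  r <- rank(scores)
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Five-metric evaluation of a fold or test set
#'
#' Sensitivity SEN = TP/(TP+FN), specificity SPE = TN/(TN+FP), accuracy
#' ACC = (TP+TN)/total, Matthews correlation
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)) with the
#' convention MCC = 0 when any denominator factor vanishes, and the
#' rank-statistic AUROC.
#'
#' @param counts confusion counts (see [confusion_counts()]).
#' @param scores,labels optional scores and labels for the AUROC; when
#'   omitted, AUROC is `NA`.
#' @return A one-row `data.frame` with columns `SEN`, `SPE`, `ACC`, `MCC`,
#'   `AUROC`.
#' @export
compute_metrics <- function(counts, scores = NULL, labels = NULL) {
  tp <- as.numeric(counts$TP); tn <- as.numeric(counts$TN)
  fp <- as.numeric(counts$FP); fn <- as.numeric(counts$FN)
  total <- tp + tn + fp + fn
  if (total <= 0) stop("confusion counts are empty")
  sen <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spe <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / total
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / sqrt(denom)
  auc <- if (is.null(scores)) NA_real_ else auroc(scores, labels)
  data.frame(SEN = sen, SPE = spe, ACC = acc, MCC = mcc, AUROC = auc)
}

#' Evaluate scored predictions against labels
#'
#' Convenience wrapper: thresholds at 0.5 for the confusion-based metrics
#' and computes the AUROC from the raw scores.
#'
#' @inheritParams confusion_counts
#' @return A one-row metric `data.frame` (see [compute_metrics()]).
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5) {
  compute_metrics(confusion_counts(scores, labels, threshold), scores, labels)
}
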