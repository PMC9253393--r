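#' Area under the ROC curve (trapezoidal rule)
#'
#' Computes the empirical ROC curve over the distinct score thresholds (ties
#' grouped) and integrates it by the trapezoidal rule, which equals the
#' Mann-Whitney statistic with ties counted half.
#'
#' @param scores Numeric predicted scores.
#' @param labels 0/1 labels.
#' @return AUC in `[0, 1]`, `NA` if only one class is present.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  idx <- cumsum(rle(s)$lengths)       # last index of each tie group
  tpr <- c(0, cumsum(y)[idx] / np)
  fpr <- c(0, cumsum(1 - y)[idx] / nn)
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

#' Area under the precision-recall curve (step interpolation)
#'
#' Walks the distinct score thresholds in decreasing order and accumulates
#' `(recall_i - recall_{i-1}) * precision_i` — the step-wise (average
#' precision) integral of the empirical PR curve.
#'
#' @inheritParams roc_auc
#' @return PR-AUC in `[0, 1]`, `NA` if no positives are present.
#' @export
pr_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  np <- sum(labels == 1)
  if (np == 0 || np == length(labels)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  idx <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[idx]
  pred_pos <- idx
  recall <- tp / np
  precision <- tp / pred_pos
  sum(diff(c(0, recall)) * precision)
}

#' Six-metric evaluation of predicted probabilities
#'
#' Sensitivity, specificity, accuracy and F1 at a fixed classification
#' threshold, plus threshold-free ROC-AUC ([roc_auc()]) and PR-AUC
#' ([pr_auc()]). With a single-class label vector the AUCs are reported as
#' missing rather than raising an error.
#'
#' @param prob Predicted event probabilities.
#' @param labels 0/1 labels.
#' @param threshold Classification threshold (default 0.5).
#' @return One-row data.frame with `sensitivity`, `specificity`, `accuracy`,
#'   `f1`, `roc_auc`, `pr_auc`.
#' @export
evaluate_scores <- function(prob, labels, threshold = 0.5) {
  stopifnot(length(prob) == length(labels), all(labels %in% c(0, 1)))
  if (!length(prob)) stop_bad_arg("empty evaluation set")
  pred <- as.integer(prob >= threshold)
  tp <- sum(pred == 1 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  data.frame(
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    accuracy = (tp + tn) / length(labels),
    f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_,
    roc_auc = roc_auc(prob, labels),
    pr_auc = pr_auc(prob, labels)
  )
}
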