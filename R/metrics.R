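## Classification metrics.

#' Area under the ROC curve
#'
#' Rank-based estimator: the probability that a randomly chosen positive
#' scores above a randomly chosen negative, with ties counted as one half
#' (equivalent to the Mann-Whitney U statistic divided by n1*n0).
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels 0/1 labels.
#' @return AUC in \[0, 1\].
#' @export
metric_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  assert_that(n1 > 0 && n0 > 0, "AUC undefined: a class is missing")
  r <- rank(scores)  # midranks for ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Standard binary classification metrics
#'
#' Accuracy at a fixed probability threshold, recall (sensitivity) and F1 of
#' the positive class, and rank-based AUC.
#'
#' @param prob predicted probability of class 1.
#' @param labels 0/1 labels.
#' @param threshold classification threshold on `prob` (default 0.5).
#' @return named list `auc`, `acc`, `f1`, `recall`.
#' @export
classification_metrics <- function(prob, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  pred <- as.integer(prob >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(auc = metric_auc(prob, labels),
       acc = mean(pred == labels),
       f1 = f1,
       recall = recall)
}

eval_report_row <- function(model_name, split, prob, labels) {
  m <- classification_metrics(prob, labels)
  data.frame(model = model_name, split = split, n = length(labels),
             auc = m$auc, acc = m$acc, f1 = m$f1, recall = m$recall)
}
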