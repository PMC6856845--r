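# Binary-classification metrics used throughout the comparison protocol.

#' Classification metrics: MCC, recall, precision, ROC AUC
#'
#' Computes the Matthews correlation coefficient
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) / \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}
#' (0 when any denominator factor vanishes), recall TP/(TP+FN), precision
#' TP/(TP+FP), and the ROC AUC from the score ranking with the midrank
#' convention for ties (random-forest probabilities and binary
#' substructure scores are heavily tied).
#'
#' @param labels Logical vector: TRUE for the positive (CIAT) class.
#' @param scores Numeric ranking scores (probabilities, pBSF, 0/1).
#' @param predictions Logical vector of predicted classes; defaults to
#'   `scores >= 0.5`.
#' @return List with `tp`, `fp`, `tn`, `fn`, `mcc`, `recall`, `precision`,
#'   `auc`, `n`.
#' @export
compute_metrics <- function(labels, scores, predictions = scores >= 0.5) {
  if (length(labels) == 0) stop("empty label set")
  stopifnot(length(scores) == length(labels),
            length(predictions) == length(labels))
  labels <- as.logical(labels); predictions <- as.logical(predictions)
  tp <- sum(predictions & labels)
  fp <- sum(predictions & !labels)
  tn <- sum(!predictions & !labels)
  fn <- sum(!predictions & labels)
  den <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       mcc = mcc, recall = recall, precision = precision,
       auc = roc_auc(labels, scores), n = length(labels))
}

#' @rdname compute_metrics
#' @return For `roc_auc`, the area under the ROC curve (midrank tie
#'   convention), or `NA` when only one class is present.
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)  # midranks
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
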