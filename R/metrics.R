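#' Binary-classification metric bundle
#'
#' Computes, for a positive class coded 1: precision = TP/(TP+FP),
#' recall = TP/(TP+FN), their harmonic-mean F1, accuracy, the Matthews
#' correlation coefficient
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))
#' (defined as 0 whenever a factor under the root is 0), AUROC by the
#' rank-sum (Mann-Whitney) formulation with midrank tie correction, and
#' AUPR as the step-wise integral of the precision-recall curve
#' (precision stepped at each distinct score threshold, i.e. average
#' precision). Precision (and hence F1) is 0 when nothing is predicted
#' positive. When `y_true` contains a single class, AUROC and AUPR are
#' undefined and reported as NA rather than 0.
#'
#' @param y_true 0/1 vector of reference labels.
#' @param y_pred 0/1 vector of predicted labels.
#' @param y_score numeric vector monotone in predicted positive-class
#'   confidence; defaults to `y_pred`.
#' @return named numeric vector: tp, tn, fp, fn, precision, recall, f1,
#'   accuracy, mcc, auroc, aupr.
#' @export
compute_metrics <- function(y_true, y_pred, y_score = y_pred) {
  stopifnot(length(y_true) == length(y_pred),
            length(y_true) == length(y_score))
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (!all(c(y_true, y_pred) %in% 0:1))
    stopf("y_true and y_pred must be coded 0/1")
  tp <- sum(y_true == 1 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  denom <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom > 0) (tp * tn - fp * fn) / denom else 0
  c(tp = tp, tn = tn, fp = fp, fn = fn,
    precision = precision, recall = recall, f1 = f1,
    accuracy = (tp + tn) / length(y_true), mcc = mcc,
    auroc = auroc(y_true, y_score), aupr = aupr(y_true, y_score))
}

#' Area under the ROC curve (rank formulation, tie-corrected)
#' @param y_true 0/1 labels; @param y_score scores.
#' @return AUROC in \[0,1\], or NA if y_true has a single class.
#' @export
auroc <- function(y_true, y_score) {
  n_pos <- sum(y_true == 1); n_neg <- sum(y_true == 0)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(y_score)                      # midranks handle ties
  (sum(r[y_true == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (step-wise integral)
#'
#' Thresholds sweep the distinct score values from high to low; tied scores
#' enter together. The integral is sum over thresholds of
#' (recall step) * (precision at that threshold) -- average precision.
#'
#' @param y_true 0/1 labels; @param y_score scores.
#' @return AUPR in \[0,1\], or NA if y_true has a single class.
#' @export
aupr <- function(y_true, y_score) {
  n_pos <- sum(y_true == 1)
  if (n_pos == 0 || n_pos == length(y_true)) return(NA_real_)
  ord <- order(y_score, decreasing = TRUE)
  yt <- y_true[ord]; ys <- y_score[ord]
  cum_tp <- cumsum(yt)
  cum_pp <- seq_along(yt)
  # last index of each tied-score block = a valid threshold
  block_end <- which(ys != c(ys[-1], NA) | seq_along(ys) == length(ys))
  prec <- cum_tp[block_end] / cum_pp[block_end]
  rec <- cum_tp[block_end] / n_pos
  sum(diff(c(0, rec)) * prec)
}
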