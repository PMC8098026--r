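# Threshold-free ranking metrics and best-F1 threshold selection.
# Implementations are self-contained rank-statistic / step-function forms and
# are cross-checked against brute-force oracles in the test suite.

#' ROC-AUC (rank statistic)
#'
#' Computed as `P(score_pos > score_neg) + 0.5 P(tie)` via the Mann-Whitney
#' rank form; invariant under strictly monotone transforms of the scores.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (both classes must be present).
#' @return ROC-AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("ROC-AUC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' PR-AUC (average precision)
#'
#' Step-wise integral of precision over recall, evaluated at the distinct
#' score thresholds in descending order (tied scores enter as one block):
#' `AP = sum_i (R_i - R_{i-1}) P_i`.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (at least one positive).
#' @return Average precision in [0, 1].
#' @export
pr_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1)
  if (n_pos == 0) stop("PR-AUC needs at least one positive")
  thr <- sort(unique(scores), decreasing = TRUE)
  ap <- 0
  prev_recall <- 0
  tp <- 0
  n_pred <- 0
  for (t in thr) {
    sel <- scores == t
    tp <- tp + sum(labels[sel] == 1)
    n_pred <- n_pred + sum(sel)
    recall <- tp / n_pos
    precision <- tp / n_pred
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

#' Select the decision threshold maximizing F1 on validation data
#'
#' Candidate thresholds are the midpoints of consecutive sorted unique scores
#' plus one candidate below the minimum (predict everything positive).  A
#' score is classified positive when `score >= threshold`.  Ties in F1 go to
#' the lowest threshold.
#'
#' @param scores Validation scores.
#' @param labels Validation labels.
#' @return The selected threshold.
#' @export
select_threshold <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-length(u)] + u[-1]) / 2)
  f1 <- vapply(cand, function(t) {
    pred <- as.integer(scores >= t)
    tp <- sum(pred == 1 & labels == 1)
    fp <- sum(pred == 1 & labels == 0)
    fn <- sum(pred == 0 & labels == 1)
    if (tp == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  cand[which.max(f1)]   # which.max returns the first (lowest) maximizer
}

#' Evaluate scored predictions at a fixed threshold
#'
#' @param scores Test-set scores.
#' @param labels Test-set labels.
#' @param threshold Decision threshold (derived from validation data).
#' @return An `eval_report` list: `roc_auc`, `pr_auc`, `sensitivity`,
#'   `specificity`, `threshold`, `n_pos`, `n_neg`.
#' @export
evaluate_scores <- function(scores, labels, threshold) {
  if (length(scores) == 0) stop("empty evaluation set")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  structure(list(roc_auc = roc_auc(scores, labels),
                 pr_auc = pr_auc(scores, labels),
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                 threshold = threshold,
                 n_pos = sum(labels == 1),
                 n_neg = sum(labels == 0)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("ROC-AUC %.3f | PR-AUC %.3f | sensitivity %.3f | ",
                     "specificity %.3f (threshold %.3f; %d pos / %d neg)\n"),
              x$roc_auc, x$pr_auc, x$sensitivity, x$specificity,
              x$threshold, x$n_pos, x$n_neg))
  invisible(x)
}
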