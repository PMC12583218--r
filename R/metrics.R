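#' Area under the ROC curve
#'
#' Rank-based (Wilcoxon) computation with ties handled by average rank;
#' equivalent to the probability that a random positive outscores a random
#' negative, counting ties as one half.
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores, higher = more likely positive.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  labels <- as.integer(labels)
  np <- sum(labels == 1L)
  nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) dti_stop("auroc needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve
#'
#' Step-wise interpolated area: thresholds sweep the distinct score values
#' in decreasing order (tied scores enter as one block) and each recall
#' increment is weighted by the precision at that operating point. With all
#' scores tied this reduces to the positive prevalence.
#'
#' @inheritParams auroc
#' @return AUPR in [0, 1].
#' @export
aupr <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  labels <- as.integer(labels)
  np <- sum(labels == 1L)
  if (np == 0L) dti_stop("aupr needs at least one positive")
  ord <- order(-scores)
  lab <- labels[ord]
  sc <- scores[ord]
  # group tied scores into single operating points
  grp_end <- which(diff(sc) != 0)
  ends <- c(grp_end, length(sc))
  tp <- cumsum(lab)[ends]
  pp <- ends
  prec <- tp / pp
  rec <- tp / np
  drec <- diff(c(0, rec))
  sum(drec * prec)
}

#' F1 score at a threshold
#'
#' Predicts positive where `score >= threshold`; returns the harmonic mean
#' of precision and recall, 0 when precision + recall is 0.
#'
#' @inheritParams auroc
#' @param threshold decision threshold on the score scale.
#' @return F1 in [0, 1].
#' @export
f1_at_threshold <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(labels)
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1L)
  fp <- sum(pred & labels == 0L)
  fn <- sum(!pred & labels == 1L)
  if (tp + fp == 0L || tp + fn == 0L) return(0)
  p <- tp / (tp + fp)
  r <- tp / (tp + fn)
  if (p + r == 0) return(0)
  2 * p * r / (p + r)
}

#' Threshold maximizing F1 over observed operating points
#' @inheritParams auroc
#' @return the score threshold with the highest F1 (ties: highest threshold).
#' @export
best_f1_threshold <- function(labels, scores) {
  cand <- sort(unique(scores), decreasing = TRUE)
  f1s <- vapply(cand, function(th) f1_at_threshold(labels, scores, th), numeric(1))
  cand[which.max(f1s)]
}

#' Precision among the top-k predictions
#'
#' Fraction of positives among the k highest-scored items; ties are broken
#' deterministically by item id.
#'
#' @inheritParams auroc
#' @param k number of top predictions (1 <= k <= length(labels)).
#' @param ids optional ids used for deterministic tie-breaking (defaults to
#'   position).
#' @return precision in [0, 1].
#' @export
precision_at_k <- function(labels, scores, k = 10L, ids = NULL) {
  if (k <= 0L) dti_stop("k must be positive")
  k <- min(k, length(labels))
  if (is.null(ids)) ids <- seq_along(labels)
  ord <- order(-scores, ids)
  mean(as.integer(labels)[ord[seq_len(k)]])
}

#' Full metric report
#' @inheritParams auroc
#' @param k top-k cutoff for precision-at-k (default 10).
#' @param f1_threshold threshold for F1; default = best operating point on
#'   these labels/scores (pass a validation-chosen threshold for honest test
#'   evaluation).
#' @return named list auroc, aupr, f1, p_at_k.
#' @export
metric_report <- function(labels, scores, k = 10L, f1_threshold = NULL) {
  if (is.null(f1_threshold)) f1_threshold <- best_f1_threshold(labels, scores)
  list(auroc = auroc(labels, scores),
       aupr = aupr(labels, scores),
       f1 = f1_at_threshold(labels, scores, f1_threshold),
       p_at_k = precision_at_k(labels, scores, k))
}
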