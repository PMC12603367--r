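# Evaluation metrics: protein-centric Fmax (CAFA convention, 0.01
# threshold grid), micro-averaged AUPR by step-wise summation, MCC with
# the degenerate-denominator-to-zero convention, and Spearman's rho as
# Pearson on average ranks.

#' Protein-centric maximum F-measure (Fmax)
#'
#' Over thresholds `t = 0.00, 0.01, ..., 1.00`: a term is predicted for a
#' protein when its score is at least `t`.  Precision at `t` is averaged
#' over proteins with at least one predicted term; recall is averaged
#' over proteins with at least one true term.  `Fmax` is the maximum of
#' `2pr/(p+r)`; thresholds at which no protein has a prediction
#' contribute `F = 0`, so an all-zero score matrix yields 0.
#'
#' @param truth Binary `proteins x terms` matrix.
#' @param scores Numeric matrix of the same shape with scores in [0, 1].
#' @return List with `fmax` and the `threshold` achieving it.
#' @export
fmax <- function(truth, scores) {
  truth <- as.matrix(truth); scores <- as.matrix(scores)
  if (!all(dim(truth) == dim(scores))) stop("shape mismatch", call. = FALSE)
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]", call. = FALSE)
  has_true <- rowSums(truth) > 0
  if (!any(has_true)) stop("undefined metric: no protein has a true term", call. = FALSE)
  thresholds <- seq(0, 1, by = 0.01)
  best <- -Inf; best_t <- 0
  for (t in thresholds) {
    pred <- scores >= t
    npred <- rowSums(pred)
    tp <- rowSums(pred & truth == 1)
    covered <- npred > 0
    if (!any(covered)) { f <- 0 } else {
      p <- mean(tp[covered] / npred[covered])
      r <- mean(tp[has_true] / rowSums(truth)[has_true])
      f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    }
    if (f > best) { best <- f; best_t <- t }
  }
  list(fmax = best, threshold = best_t)
}

#' Area under the precision-recall curve (micro-averaged)
#'
#' Flattens all protein-term pairs, sweeps the distinct score values in
#' decreasing order (ties grouped into a single step), and sums
#' `(R_k - R_{k-1}) * P_k` without interpolation.
#'
#' @param truth Binary vector (or matrix, flattened) of true labels.
#' @param scores Real-valued scores of the same length.
#' @return Scalar AUPR in [0, 1].
#' @export
aupr <- function(truth, scores) {
  truth <- as.vector(as.matrix(truth)); scores <- as.vector(as.matrix(scores))
  if (length(truth) != length(scores)) stop("length mismatch", call. = FALSE)
  n_pos <- sum(truth == 1)
  if (n_pos == 0) stop("undefined metric: no positive labels", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  truth <- truth[ord]; scores <- scores[ord]
  cum_tp <- cumsum(truth == 1)
  cum_n <- seq_along(truth)
  # last index of each tie group = the PR point for that threshold
  last <- which(!duplicated(scores, fromLast = TRUE))
  precision <- cum_tp[last] / cum_n[last]
  recall <- cum_tp[last] / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; defined as 0
#' whenever a factor of the denominator is 0.
#'
#' @param truth,pred Binary vectors of equal length.
#' @return Scalar MCC in [-1, 1].
#' @export
mcc <- function(truth, pred) {
  truth <- as.vector(as.matrix(truth)); pred <- as.vector(as.matrix(pred))
  if (length(truth) != length(pred)) stop("length mismatch", call. = FALSE)
  tp <- sum(truth == 1 & pred == 1); tn <- sum(truth == 0 & pred == 0)
  fp <- sum(truth == 0 & pred == 1); fn <- sum(truth == 1 & pred == 0)
  denom <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom)
}

#' Spearman's rank correlation
#'
#' Pearson correlation of average-ranked values (ties receive their mean
#' rank).  Errors on constant input, where ranks carry no information.
#'
#' @param a,b Numeric vectors of equal length (>= 3).
#' @return Scalar rho in [-1, 1].
#' @export
spearman_rho <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  if (length(a) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (length(unique(a)) < 2L || length(unique(b)) < 2L) {
    stop("undefined metric: constant input", call. = FALSE)
  }
  cor(rank(a, ties.method = "average"), rank(b, ties.method = "average"))
}

#' Classification accuracy
#'
#' @param truth,pred Vectors of equal length (class labels or indices).
#' @return Fraction of agreeing entries.
#' @export
accuracy <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("length mismatch", call. = FALSE)
  mean(truth == pred)
}
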