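## Evaluation metrics for label prediction and gene prioritisation, plus
## the fold-change and Welch t-test baseline scorers.

check_same_length <- function(a, b) {
  if (length(a) != length(b))
    stop("length mismatch: ", length(a), " vs ", length(b))
}

#' Hamming loss of single-label predictions
#'
#' Mean indicator-cell mismatch between the one-hot encodings of
#' predicted and true labels: \eqn{(1/(nc))\sum_i\sum_j |h_{ij} - y_{ij}|}.
#' For single-label data this equals \eqn{2/c} times the
#' misclassification rate; 0 is perfect.
#'
#' @param pred,truth Integer label vectors in \code{1..n_categories}.
#' @param n_categories Number of categories c.
#' @return A number in [0, 1].
#' @export
hamming_loss <- function(pred, truth, n_categories) {
  check_same_length(pred, truth)
  if (any(c(pred, truth) < 1) || any(c(pred, truth) > n_categories))
    stop("labels must lie in 1..n_categories")
  mean(abs(one_hot(pred, n_categories) - one_hot(truth, n_categories)))
}

#' One-error of a category score matrix
#'
#' Fraction of samples whose top-scoring category (ties to the smallest
#' index) is not the true one.
#'
#' @param scores n-by-c matrix of per-category scores.
#' @param truth Integer true labels.
#' @return A number in [0, 1].
#' @export
one_error <- function(scores, truth) {
  check_same_length(scores[, 1L], truth)
  mean(max.col(scores, ties.method = "first") != truth)
}

#' Coverage of a category score matrix
#'
#' Mean over samples of how many steps down the descending score ranking
#' one must go past the first position to reach the true category
#' (rank - 1, ties broken toward the smaller category index); 0 when the
#' true label always ranks first, c - 1 at worst.
#'
#' @inheritParams one_error
#' @return A non-negative number.
#' @export
coverage <- function(scores, truth) {
  check_same_length(scores[, 1L], truth)
  ranks <- vapply(seq_len(nrow(scores)), function(i) {
    ord <- order(-scores[i, ], seq_len(ncol(scores)))
    which(ord == truth[i])
  }, 1L)
  mean(ranks - 1)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a uniformly chosen
#' positive item outscores a uniformly chosen negative one, ties counted
#' one half.
#'
#' @param scores Numeric scores, higher = more confidently positive.
#' @param truth Binary labels (0/1 or logical); both classes must be
#'   present.
#' @return A number in [0, 1].
#' @export
roc_auc <- function(scores, truth) {
  check_same_length(scores, truth)
  truth <- as.integer(as.logical(truth))
  np <- sum(truth == 1L)
  nn <- sum(truth == 0L)
  if (np == 0L || nn == 0L)
    stop("both a positive and a negative item are required")
  r <- rank(scores)  # average ranks handle ties as 1/2
  (sum(r[truth == 1L]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve
#'
#' Step-curve area over descending-score thresholds (one threshold per
#' distinct score, no interpolation): the sum over thresholds of the
#' recall gained there times the precision at that threshold.
#'
#' @inheritParams roc_auc
#' @param truth Binary labels with at least one positive.
#' @return A number in (0, 1].
#' @export
aupr <- function(scores, truth) {
  check_same_length(scores, truth)
  truth <- as.integer(as.logical(truth))
  p <- sum(truth == 1L)
  if (p == 0L) stop("at least one positive item is required")
  o <- order(scores, decreasing = TRUE)
  y <- truth[o]
  s <- scores[o]
  tp <- cumsum(y)
  n_seen <- seq_along(y)
  at <- which(!duplicated(s, fromLast = TRUE))  # last index of each tie group
  recall <- tp[at] / p
  precision <- tp[at] / n_seen[at]
  sum(diff(c(0, recall)) * precision)
}

resolve_group <- function(x, group) {
  idx <- if (is.character(group)) match(group, rownames(x)) else group
  if (anyNA(idx)) stop("unknown sample id(s) in group")
  idx
}

#' Per-gene absolute log2 fold change between two sample groups
#'
#' @param x Samples-by-genes matrix.
#' @param group_a,group_b Disjoint, non-empty sets of sample ids (or row
#'   indices).
#' @param pseudocount Added to both group means before the ratio.
#' @return Named numeric vector, one score per gene; higher = more
#'   differential.
#' @export
fold_change_scores <- function(x, group_a, group_b, pseudocount = 0) {
  a <- resolve_group(x, group_a)
  b <- resolve_group(x, group_b)
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  if (length(intersect(a, b))) stop("groups must be disjoint")
  ma <- colMeans(x[a, , drop = FALSE])
  mb <- colMeans(x[b, , drop = FALSE])
  abs(log2((ma + pseudocount) / (mb + pseudocount)))
}

#' Per-gene absolute Welch t statistic between two sample groups
#'
#' Unequal-variance (Welch) t statistic per gene; a gene with equal
#' group means scores 0 even when both variances vanish.
#'
#' @inheritParams fold_change_scores
#' @return Named numeric vector of |t| values.
#' @export
t_test_scores <- function(x, group_a, group_b) {
  a <- resolve_group(x, group_a)
  b <- resolve_group(x, group_b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 samples")
  if (length(intersect(a, b))) stop("groups must be disjoint")
  xa <- x[a, , drop = FALSE]
  xb <- x[b, , drop = FALSE]
  num <- colMeans(xa) - colMeans(xb)
  se2 <- apply(xa, 2L, stats::var) / length(a) +
    apply(xb, 2L, stats::var) / length(b)
  t <- abs(num) / sqrt(se2)
  t[abs(num) == 0] <- 0  # covers the 0/0 case at constant equal genes
  t
}
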