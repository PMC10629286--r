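#' Average precision (area under the precision-recall curve)
#'
#' Computes average precision for a ranked set of predictions: the mean, over
#' positives, of the precision at each positive's rank. This is the primary
#' classification metric used throughout the benchmarks because gene
#' prediction tasks are extremely class-imbalanced, where the PR curve is far
#' more informative than ROC.
#'
#' Ties are handled explicitly because auPRC comparisons across embeddings
#' are the core readout of the benchmark suite:
#' \describe{
#'   \item{`"stable"`}{items are sorted by decreasing score with ties broken
#'     by original input position (a documented, deterministic order).}
#'   \item{`"grouped"`}{items sharing a score are treated as a single
#'     threshold step; each group contributes `delta_TP * precision_at_group_end`.
#'     This is invariant to the input order of tied items.}
#' }
#'
#' @param score numeric vector of predicted scores (higher = more positive).
#' @param label 0/1 vector (or logical) of true labels, parallel to `score`.
#' @param ties one of `"stable"`, `"grouped"`.
#' @return scalar in \[0, 1\].
#' @export
average_precision <- function(score, label, ties = c("stable", "grouped")) {
  ties <- match.arg(ties)
  stopifnot(length(score) == length(label))
  label <- as.integer(as.logical(label))
  if (anyNA(score) || anyNA(label)) stop("NA in scores or labels")
  P <- sum(label)
  if (P == 0L || P == length(label)) {
    stop("average_precision needs at least one positive and one negative")
  }
  if (ties == "stable") {
    ord <- order(-score, seq_along(score))
    lab <- label[ord]
    tp <- cumsum(lab)
    prec <- tp / seq_along(lab)
    sum(prec[lab == 1L]) / P
  } else {
    ord <- order(-score)
    lab <- label[ord]
    s <- score[ord]
    grp_end <- which(diff(s) != 0)
    grp_end <- c(grp_end, length(s))
    tp <- cumsum(lab)[grp_end]
    n_at <- grp_end
    prec <- tp / n_at
    dtp <- diff(c(0, tp))
    sum(dtp * prec) / P
  }
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney U statistic divided by `n_pos * n_neg`;
#' average ranks give tied pairs a contribution of 1/2.
#'
#' @inheritParams average_precision
#' @return scalar in \[0, 1\].
#' @export
roc_auc <- function(score, label) {
  stopifnot(length(score) == length(label))
  label <- as.integer(as.logical(label))
  n1 <- sum(label)
  n0 <- sum(1L - label)
  if (n1 == 0L || n0 == 0L) stop("roc_auc needs at least one positive and one negative")
  r <- rank(score, ties.method = "average")
  (sum(r[label == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Paired two-sided Wilcoxon signed-rank test
#'
#' The cross-embedding comparison used everywhere in the benchmark reports.
#' Zero differences are dropped; the exact null distribution is used for
#' n <= 25 non-zero untied pairs, otherwise the normal approximation with
#' continuity correction. Identical vectors (no non-zero pairs) return
#' p = 1 by convention.
#'
#' @param a,b paired numeric vectors.
#' @return two-sided p-value.
#' @export
paired_wilcoxon <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  exact <- n <= 25 && !anyDuplicated(abs(d))
  res <- suppressWarnings(
    stats::wilcox.test(d, alternative = "two.sided", exact = exact, correct = TRUE)
  )
  unname(res$p.value)
}

#' Spearman rank correlation test
#'
#' Rank correlation with average ranks for ties; p-value from the
#' t-distribution approximation.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `rho` and `p`.
#' @export
spearman_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  res <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  list(rho = unname(res$estimate), p = unname(res$p.value))
}

#' Jaccard index of two sets
#'
#' `|A intersect B| / |A union B|`; two empty sets give 0 by convention.
#'
#' @param a,b vectors treated as sets.
#' @return scalar in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}
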