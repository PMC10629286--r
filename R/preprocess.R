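#' Log-transform and per-gene mean-centre an expression matrix
#'
#' The standard preprocessing for TPM-like abundance matrices before tensor
#' factorization: `log(x + pseudocount)` followed by subtracting each gene's
#' row mean. The pseudocount (default 1) guards the log against the zeros
#' that TPM matrices contain; the log base is natural.
#'
#' Applying the transform twice is not a no-op (the second log re-transforms
#' already-log values) but the per-gene mean-zero post-condition is
#' re-established by any application.
#'
#' @param m an [expression_matrix()] with non-negative values.
#' @param pseudocount added before the log; default 1.
#' @return an [expression_matrix()] with per-gene mean 0.
#' @export
preprocess_expression <- function(m, pseudocount = 1) {
  stopifnot(inherits(m, "expression_matrix"))
  if (any(m$values < 0)) stop("negative values: preprocess_expression expects raw abundances")
  v <- log(m$values + pseudocount)
  v <- v - rowMeans(v)
  out <- m
  out$values <- v
  out
}

#' Drop samples (columns) from an expression matrix by id
#'
#' Generic sample exclusion, e.g. removing a handful of cell lines known to
#' cause multicollinearity in an essentiality screen. Unknown ids are an
#' error; dropping all samples is an error.
#'
#' @param m an [expression_matrix()].
#' @param sample_ids character vector of column ids to remove.
#' @return an [expression_matrix()] without those columns.
#' @export
drop_samples <- function(m, sample_ids) {
  stopifnot(inherits(m, "expression_matrix"))
  idx <- match(sample_ids, m$sample_ids)
  if (anyNA(idx)) stop("unknown sample id(s): ",
                       paste(sample_ids[is.na(idx)], collapse = ", "))
  if (length(idx) >= ncol(m$values)) stop("cannot drop every sample")
  out <- m
  out$values <- m$values[, -idx, drop = FALSE]
  out$sample_ids <- m$sample_ids[-idx]
  out
}

#' Remove principal components computed on a gene subset
#'
#' Removes global technical variation the way essentiality screens are
#' cleaned: principal axes are computed from the profiles of a designated
#' gene subset expected to carry no biological signal for the assay (e.g.
#' olfactory receptor genes in a cancer cell-line screen), and the
#' projection of every gene's profile onto the first `k` of those axes is
#' subtracted.
#'
#' @param m an [expression_matrix()].
#' @param subset a [gene_list()] defining the genes the axes are computed on.
#' @param k number of components to remove (default 4); `k = 0` is the
#'   identity transform.
#' @return an [expression_matrix()] of identical shape and gene mask.
#' @export
remove_gene_subset_pcs <- function(m, subset, k = 4) {
  stopifnot(inherits(m, "expression_matrix"), inherits(subset, "gene_list"))
  if (k == 0L) return(m)
  sub_ids <- intersect(subset$genes, rownames(m$values))
  if (length(sub_ids) == 0L) stop("no subset gene present in the matrix")
  if (k >= ncol(m$values)) stop("k must be smaller than the number of samples")
  sub <- m$values[sub_ids, , drop = FALSE]
  mu <- colMeans(sub)
  sub_c <- sweep(sub, 2, mu)
  sv <- svd(sub_c, nu = 0)
  r <- sum(sv$d > max(dim(sub_c)) * max(sv$d) * .Machine$double.eps)
  if (k >= r) stop("k (", k, ") >= rank of subset submatrix (", r, ")")
  V <- sv$v[, seq_len(k), drop = FALSE]             # axes in sample space
  centred <- sweep(m$values, 2, mu)
  proj <- centred %*% V %*% t(V)
  out <- m
  out$values <- m$values - proj
  out
}
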