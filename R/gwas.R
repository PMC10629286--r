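# LD-aware GWAS z-score regression: Cholesky whitening and
# leave-one-chromosome-out elastic-net evaluation.

#' Whiten a regression problem against a residual covariance
#'
#' With `R = L L'` (lower Cholesky), returns `L^-1 y`, `L^-1 C`, `L^-1 X`
#' so that residuals distributed `MVN(0, R)` become `MVN(0, I)` and an
#' ordinary penalised regression applies. Applied blockwise per chromosome
#' by [gwas_loco_fit()]. If `R` is not positive definite a jitter of
#' `1e-8 * I` is added once (with a message); failure after the jitter is
#' an error.
#'
#' @param y response vector.
#' @param C covariate matrix (rows align with `y`).
#' @param X feature matrix (rows align with `y`); may be `NULL`.
#' @param R symmetric positive-definite residual covariance.
#' @return list with `y`, `C`, `X` (whitened) and `L` (the lower Cholesky
#'   factor, needed to map predictions back to the original scale).
#' @export
whiten <- function(y, C, X, R) {
  stopifnot(length(y) == nrow(R), nrow(C) == length(y))
  U <- tryCatch(chol(R), error = function(e) {
    message("residual covariance not PD; adding 1e-8 jitter")
    tryCatch(chol(R + diag(1e-8, nrow(R))),
             error = function(e2) stop("covariance not PD after jitter"))
  })
  L <- t(U)
  wy <- forwardsolve(L, y)
  wC <- forwardsolve(L, C)
  colnames(wC) <- colnames(C)
  wX <- if (is.null(X)) NULL else {
    out <- forwardsolve(L, X)
    colnames(out) <- colnames(X)
    out
  }
  list(y = wy, C = wC, X = wX, L = L)
}

# whiten all chromosomes of a score set restricted to `genes`; returns
# stacked whitened design plus the per-chromosome L factors
.whiten_by_chrom <- function(scores, genes, X) {
  chroms <- sort(unique(scores$chromosome[genes]))
  parts <- lapply(chroms, function(ch) {
    g <- genes[scores$chromosome[genes] == ch]
    R <- scores$R_blocks[[as.character(ch)]][g, g, drop = FALSE]
    w <- whiten(scores$y[g], scores$C[g, , drop = FALSE],
                X[g, , drop = FALSE], R)
    list(genes = g, chrom = ch, w = w)
  })
  parts
}

#' Leave-one-chromosome-out GWAS signal regression
#'
#' Evaluates how much a functional gene embedding improves the prediction
#' of gene-level association z-scores over gene-level covariates alone.
#' For each held-out chromosome, training and test blocks are whitened per
#' chromosome with [whiten()], an elastic net is fitted on the whitened
#' covariates plus embedding (hyperparameters chosen by grouped
#' cross-validation over the training chromosomes), predictions are mapped
#' back to the original scale with the held-out block's Cholesky factor,
#' and the coefficient of determination is computed over all held-out
#' genes pooled. The null model repeats the procedure with covariates
#' only; the headline quantity is `delta R^2 = R^2 - R0^2`.
#'
#' @param embedding an [embedding_matrix()].
#' @param scores a `gwas_gene_scores` object (see [make_gwas_scores()]).
#' @param alphas elastic-net mixing grid (default 0.1, 0.5, 0.9).
#' @param nlambda glmnet lambda path length (default 30).
#' @return list with `delta_r2`, `r2`, `r0_2` and `per_gene` (data.frame:
#'   gene, chromosome, publication-independent fields `y`, `pred_full`,
#'   `pred_null`).
#' @export
gwas_loco_fit <- function(embedding, scores, alphas = c(0.1, 0.5, 0.9),
                          nlambda = 30) {
  stopifnot(inherits(embedding, "embedding_matrix"),
            inherits(scores, "gwas_gene_scores"))
  genes <- intersect(rownames(embedding$values), scores$gene_ids)
  if (length(genes) < 10) stop("too few genes shared by embedding and scores")
  chroms <- sort(unique(scores$chromosome[genes]))
  if (length(chroms) < 3) stop("need at least 3 chromosomes for LOCO")
  X <- embedding$values[genes, , drop = FALSE]

  fit_branch <- function(use_embedding) {
    per_gene <- data.frame()
    for (ch in chroms) {
      tr_genes <- genes[scores$chromosome[genes] != ch]
      te_genes <- genes[scores$chromosome[genes] == ch]
      trp <- .whiten_by_chrom(scores, tr_genes, X)
      tep <- .whiten_by_chrom(scores, te_genes, X)[[1]]
      wy <- unlist(lapply(trp, function(p) p$w$y))
      wC <- do.call(rbind, lapply(trp, function(p) p$w$C))
      wX <- do.call(rbind, lapply(trp, function(p) p$w$X))
      foldid <- unlist(lapply(seq_along(trp), function(i)
        rep(i, length(trp[[i]]$genes))))
      D <- if (use_embedding) cbind(wC, wX) else wC
      Dte <- if (use_embedding) cbind(tep$w$C, tep$w$X) else tep$w$C
      best <- NULL
      for (a in alphas) {
        cv <- glmnet::cv.glmnet(D, wy, alpha = a, foldid = foldid,
                                nlambda = nlambda)
        if (is.null(best) || min(cv$cvm) < best$err) {
          best <- list(err = min(cv$cvm), cv = cv, lambda = cv$lambda.min)
        }
      }
      pw <- stats::predict(best$cv, Dte, s = best$lambda)[, 1]
      pred <- as.numeric(tep$w$L %*% pw)     # back to the original scale
      per_gene <- rbind(per_gene, data.frame(
        gene = te_genes, chromosome = ch, y = unname(scores$y[te_genes]),
        pred = pred))
    }
    per_gene
  }

  full <- fit_branch(TRUE)
  null <- fit_branch(FALSE)
  sst <- sum((full$y - mean(full$y))^2)
  r2 <- 1 - sum((full$y - full$pred)^2) / sst
  r0 <- 1 - sum((null$y - null$pred)^2) / sst
  per_gene <- data.frame(gene = full$gene, chromosome = full$chromosome,
                         y = full$y, pred_full = full$pred,
                         pred_null = null$pred)
  list(delta_r2 = r2 - r0, r2 = r2, r0_2 = r0, per_gene = per_gene)
}

#' Coefficient-of-determination gain within a gene subset
#'
#' Helper metric for [publication_stratify()]: given pooled
#' leave-one-chromosome-out predictions, computes `R^2 - R0^2` restricted
#' to the rows supplied.
#'
#' @param per_gene data.frame with columns `y`, `pred_full`, `pred_null`.
#' @return scalar delta R^2.
#' @export
delta_r2_metric <- function(per_gene) {
  sst <- sum((per_gene$y - mean(per_gene$y))^2)
  if (sst == 0) return(NA_real_)
  (1 - sum((per_gene$y - per_gene$pred_full)^2) / sst) -
    (1 - sum((per_gene$y - per_gene$pred_null)^2) / sst)
}

#' Stratify a per-gene metric by publication count
#'
#' Ranks genes by publication count (ties broken by gene id), cuts them
#' into `n_bins` equal-size bins (sizes differ by at most one; bin 1 =
#' fewest publications), recomputes the metric within each bin — and
#' within each unit (e.g. trait) when a `unit` column is present — and
#' reports a Spearman rank-correlation test between bin index and metric
#' across all (bin, unit) records.
#'
#' @param per_gene data.frame with a `gene` column plus whatever columns
#'   `metric_fn` needs; an optional `unit` column defines replicates.
#' @param publication_counts named integer vector (gene -> count).
#' @param metric_fn function mapping a subset of `per_gene` to a scalar
#'   (default [delta_r2_metric()]).
#' @param n_bins number of publication bins (default 5).
#' @return list with `bins` (data.frame: bin, unit, metric, n_genes,
#'   min_pub, max_pub) and `trend` (list `rho`, `p`).
#' @export
publication_stratify <- function(per_gene, publication_counts,
                                 metric_fn = delta_r2_metric, n_bins = 5) {
  stopifnot("gene" %in% names(per_gene))
  genes <- unique(per_gene$gene)
  pub <- publication_counts[genes]
  if (anyNA(pub)) stop("missing publication counts for some genes")
  ord <- genes[order(pub, genes)]
  sizes <- rep(length(ord) %/% n_bins, n_bins)
  extra <- length(ord) %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bin_of <- stats::setNames(rep(seq_len(n_bins), times = sizes), ord)
  units <- if ("unit" %in% names(per_gene)) unique(per_gene$unit) else NA
  bins <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    bg <- names(bin_of)[bin_of == b]
    do.call(rbind, lapply(units, function(u) {
      sub <- per_gene[per_gene$gene %in% bg, , drop = FALSE]
      if (!is.na(u)) sub <- sub[sub$unit == u, , drop = FALSE]
      data.frame(bin = b, unit = u, metric = metric_fn(sub),
                 n_genes = length(unique(sub$gene)),
                 min_pub = min(publication_counts[bg]),
                 max_pub = max(publication_counts[bg]))
    }))
  }))
  ok <- is.finite(bins$metric)
  trend <- spearman_test(bins$bin[ok], bins$metric[ok])
  list(bins = bins, trend = trend)
}
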