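# Gene-list classification, trait deduplication, rare-variant filtering and
# multi-label phenotype prediction. Fold plans are created once per
# (task, seed) and shared across embeddings so paired comparisons are valid.

#' Create a cross-validation fold plan
#'
#' Deterministic unit -> fold assignment. A plan created with the same
#' units, fold count and seed is byte-identical, which is what makes
#' paired tests across embeddings valid: every embedding sees the same
#' folds.
#'
#' @param units character vector of unit ids (genes, traits, ...).
#' @param folds number of folds.
#' @param seed RNG seed.
#' @param scheme assignment scheme; `"random_kfold"` (balanced random) or
#'   `"gene_split"` (a single train/test split, fold 1 = test).
#' @param test_fraction test fraction for `"gene_split"`.
#' @return object of class `fold_plan`: named integer vector of fold ids.
#' @export
make_fold_plan <- function(units, folds = 5, seed = 1,
                           scheme = c("random_kfold", "gene_split"),
                           test_fraction = 0.3) {
  scheme <- match.arg(scheme)
  n <- length(units)
  ids <- with_seed(seed, {
    if (scheme == "random_kfold") {
      sample(rep_len(seq_len(folds), n))
    } else {
      out <- rep(2L, n)
      out[sample.int(n, floor(test_fraction * n))] <- 1L
      out
    }
  })
  structure(stats::setNames(as.integer(ids), units),
            scheme = scheme, seed = seed, class = "fold_plan")
}

.tune_grid_default <- function() {
  g <- 10^seq(-2, 5, length.out = 4)
  expand.grid(alpha = g, lambda = g)
}

.xgb_fit_predict <- function(Xtr, ytr, Xte, reg_alpha, reg_lambda, nrounds,
                             seed) {
  bst <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", nthread = 1,
                  alpha = reg_alpha, lambda = reg_lambda, seed = seed),
    data = xgboost::xgb.DMatrix(Xtr, label = ytr, nthread = 1),
    nrounds = nrounds, verbose = 0
  )
  stats::predict(bst, xgboost::xgb.DMatrix(Xte, nthread = 1))
}

#' Gene-list classification with gradient-boosted trees
#'
#' Trains an XGBoost classifier in k-fold cross-validation to predict
#' membership of a gene list from an embedding: list genes are positives,
#' every other embedded gene is a negative (so the negative set may contain
#' yet-to-be-discovered positives). The L1 and L2 regularisation strengths
#' are tuned by nested cross-validation over a log-spaced grid spanning
#' 1e-2 to 1e5; the metric is average precision per validation fold.
#'
#' @param embedding an [embedding_matrix()].
#' @param gene_list a [gene_list()]; must have at least `folds` genes.
#' @param folds outer folds (default 5).
#' @param seed seed for the fold plan and the boosters.
#' @param fold_plan optional precomputed [make_fold_plan()] (shared across
#'   embeddings).
#' @param tune_grid data.frame with columns `alpha`, `lambda`; `NULL`
#'   disables tuning (both penalties 1).
#' @param inner_folds inner folds for tuning (default 3).
#' @param nrounds boosting rounds (default 50).
#' @param n_novel how many top-ranked non-positive genes to report.
#' @return list with `auprc` (per fold), `scores` (out-of-fold per gene),
#'   `novel` (ranked non-positive genes), `fold_plan`, `prevalence`.
#' @export
genelist_classify <- function(embedding, gene_list, folds = 5, seed = 1,
                              fold_plan = NULL,
                              tune_grid = .tune_grid_default(),
                              inner_folds = 3, nrounds = 50, n_novel = 20) {
  stopifnot(inherits(embedding, "embedding_matrix"),
            inherits(gene_list, "gene_list"))
  X <- embedding$values
  y <- as.integer(rownames(X) %in% gene_list$genes)
  if (sum(y) < folds) stop("gene list smaller than the number of folds")
  if (is.null(fold_plan)) {
    fold_plan <- make_fold_plan(rownames(X), folds, seed)
  }
  fid <- unname(fold_plan[rownames(X)])
  oof <- rep(NA_real_, nrow(X))
  ap <- numeric(folds)
  for (k in seq_len(folds)) {
    tr <- which(fid != k); te <- which(fid == k)
    best <- list(alpha = 1, lambda = 1)
    if (!is.null(tune_grid) && nrow(tune_grid) > 1) {
      inner <- with_seed(seed + 100L + k,
                         sample(rep_len(seq_len(inner_folds), length(tr))))
      perf <- numeric(nrow(tune_grid))
      for (g in seq_len(nrow(tune_grid))) {
        aps <- numeric(inner_folds)
        for (j in seq_len(inner_folds)) {
          itr <- tr[inner != j]; ite <- tr[inner == j]
          if (sum(y[ite]) == 0 || sum(y[itr]) == 0) { aps[j] <- NA; next }
          p <- .xgb_fit_predict(X[itr, , drop = FALSE], y[itr],
                                X[ite, , drop = FALSE],
                                tune_grid$alpha[g], tune_grid$lambda[g],
                                nrounds, seed + k)
          aps[j] <- average_precision(p, y[ite])
        }
        perf[g] <- mean(aps, na.rm = TRUE)
      }
      best <- tune_grid[which.max(perf), ]
    }
    oof[te] <- .xgb_fit_predict(X[tr, , drop = FALSE], y[tr],
                                X[te, , drop = FALSE],
                                best$alpha, best$lambda, nrounds, seed + k)
    # a fold whose validation split lacks a class has no defined auPRC
    ap[k] <- if (sum(y[te]) == 0 || sum(y[te]) == length(te)) NA_real_ else
      average_precision(oof[te], y[te])
  }
  names(oof) <- rownames(X)
  novel <- names(sort(oof[y == 0], decreasing = TRUE))[seq_len(n_novel)]
  list(auprc = ap, scores = oof, novel = novel, fold_plan = fold_plan,
       prevalence = mean(y))
}

#' Gene-list classification with elastic-net logistic regression
#'
#' The high-dimensional-features counterpart of [genelist_classify()] (and
#' the model used for rare-variant trait recall): same fold plan and metric,
#' with the elastic-net mixing and strength tuned on inner folds.
#'
#' @inheritParams genelist_classify
#' @param features an [embedding_matrix()] (any feature matrix).
#' @param alphas mixing values tuned over (default 0.1, 0.5, 0.9).
#' @return list with `auprc`, `scores`, `fold_plan`, `prevalence`.
#' @export
logistic_elastic_classify <- function(features, gene_list, folds = 5,
                                      seed = 1, fold_plan = NULL,
                                      alphas = c(0.1, 0.5, 0.9)) {
  stopifnot(inherits(features, "embedding_matrix"),
            inherits(gene_list, "gene_list"))
  X <- features$values
  y <- as.integer(rownames(X) %in% gene_list$genes)
  if (sum(y) < folds) stop("gene list smaller than the number of folds")
  if (is.null(fold_plan)) {
    fold_plan <- make_fold_plan(rownames(X), folds, seed)
  }
  fid <- unname(fold_plan[rownames(X)])
  oof <- rep(NA_real_, nrow(X))
  ap <- numeric(folds)
  for (k in seq_len(folds)) {
    tr <- which(fid != k); te <- which(fid == k)
    inner <- with_seed(seed + 200L + k,
                       sample(rep_len(seq_len(3), length(tr))))
    best <- NULL
    for (a in alphas) {
      cv <- glmnet::cv.glmnet(X[tr, , drop = FALSE], y[tr],
                              family = "binomial", alpha = a,
                              foldid = inner, nlambda = 30)
      err <- min(cv$cvm)
      if (is.null(best) || err < best$err) {
        best <- list(err = err, alpha = a, lambda = cv$lambda.min, cv = cv)
      }
    }
    oof[te] <- stats::predict(best$cv, X[te, , drop = FALSE],
                              s = best$lambda, type = "response")[, 1]
    ap[k] <- if (sum(y[te]) == 0 || sum(y[te]) == length(te)) NA_real_ else
      average_precision(oof[te], y[te])
  }
  names(oof) <- rownames(X)
  list(auprc = ap, scores = oof, fold_plan = fold_plan, prevalence = mean(y))
}

#' Deduplicate similar trait gene lists
#'
#' Drops lists below `min_genes`, clusters the rest by single linkage on
#' pairwise Jaccard similarity above `jaccard_threshold` (strictly
#' greater), and keeps one representative per cluster: the largest list,
#' ties broken by name order.
#'
#' @param gene_lists list of [gene_list()] objects.
#' @param jaccard_threshold similarity threshold (default 0.3).
#' @param min_genes minimum list size retained (default 30).
#' @return the representative subset, in input order.
#' @export
dedupe_traits <- function(gene_lists, jaccard_threshold = 0.3,
                          min_genes = 30) {
  keep <- vapply(gene_lists, function(g) length(g$genes) >= min_genes,
                 logical(1))
  gene_lists <- gene_lists[keep]
  n <- length(gene_lists)
  if (n <= 1) return(gene_lists)
  # single-linkage components of the Jaccard > threshold graph
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (jaccard(gene_lists[[i]]$genes, gene_lists[[j]]$genes) >
          jaccard_threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  reps <- integer(0)
  for (r in unique(roots)) {
    members <- which(roots == r)
    sizes <- vapply(gene_lists[members], function(g) length(g$genes),
                    integer(1))
    nms <- vapply(gene_lists[members], function(g) g$name, character(1))
    reps <- c(reps, members[order(-sizes, nms)][1])
  }
  gene_lists[sort(reps)]
}

#' Filter a rare-variant association table into trait gene lists
#'
#' Keeps associations at or below the per-test significance cutoffs
#' (`<=` retains, the documented boundary convention), optionally
#' intersects with a QC gene whitelist, and deduplicates the resulting
#' trait lists with [dedupe_traits()].
#'
#' @param assoc_table data.frame with columns `gene`, `trait`, `test`
#'   (`"burden"` or `"skato"`) and `p`.
#' @param universe a [gene_universe()].
#' @param burden_cutoff,skato_cutoff significance cutoffs (defaults
#'   6.7e-7 and 2.5e-7).
#' @param whitelist optional character vector of QC-passing genes.
#' @param min_genes,jaccard_threshold passed to [dedupe_traits()].
#' @param dedupe apply [dedupe_traits()]? Default TRUE.
#' @return list of [gene_list()] objects, one per retained trait.
#' @export
genebass_filter <- function(assoc_table, universe, burden_cutoff = 6.7e-7,
                            skato_cutoff = 2.5e-7, whitelist = NULL,
                            min_genes = 30, jaccard_threshold = 0.3,
                            dedupe = TRUE) {
  stopifnot(all(c("gene", "trait", "test", "p") %in% names(assoc_table)))
  bad <- setdiff(unique(assoc_table$test), c("burden", "skato"))
  if (length(bad)) stop("unknown test type(s): ", paste(bad, collapse = ", "))
  cut <- ifelse(assoc_table$test == "burden", burden_cutoff, skato_cutoff)
  sig <- assoc_table[assoc_table$p <= cut, , drop = FALSE]
  if (!is.null(whitelist)) sig <- sig[sig$gene %in% whitelist, , drop = FALSE]
  if (nrow(sig) == 0L) return(list())
  lists <- lapply(split(sig$gene, sig$trait), unique)
  out <- Map(function(genes, nm) {
    gene_list(genes, universe, name = nm, source_tag = "rare_variant_assoc")
  }, lists, names(lists))
  out <- unname(out)
  if (dedupe) dedupe_traits(out, jaccard_threshold, min_genes) else out
}

#' Multi-label phenotype prediction with a two-layer network
#'
#' Splits genes 70/30 into train and test, trains a two-layer network
#' (hidden width = input dims / 2 by default) with binary cross-entropy and
#' Adam for a fixed number of epochs to predict the multi-hot label matrix
#' from the embedding, and reports per-term average precision and ROC AUC
#' on the held-out genes.
#'
#' @param embedding an [embedding_matrix()].
#' @param labels binary matrix genes x terms (gene-id rownames); columns
#'   with fewer than `min_genes` annotations are dropped with a message.
#' @param split train fraction (default 0.7).
#' @param epochs Adam epochs (default 500, full batch).
#' @param seed RNG seed (split, init).
#' @param hidden hidden width (default `ceiling(ncol(embedding) / 2)`).
#' @param lr Adam learning rate.
#' @param min_genes minimum annotations per term (default 20).
#' @return list with `per_term` (data.frame: term, auprc, auc, prevalence),
#'   `test_genes`, `scores` (test-gene score matrix).
#' @export
hpo_multilabel <- function(embedding, labels, split = 0.7, epochs = 500,
                           seed = 1, hidden = NULL, lr = 0.01,
                           min_genes = 20) {
  stopifnot(inherits(embedding, "embedding_matrix"), is.matrix(labels))
  genes <- intersect(rownames(embedding$values), rownames(labels))
  if (length(genes) < 10) stop("too few genes shared by embedding and labels")
  X <- embedding$values[genes, , drop = FALSE]
  Y <- labels[genes, , drop = FALSE]
  keep <- colSums(Y) >= min_genes
  if (!all(keep)) {
    message("dropping ", sum(!keep), " term(s) with < ", min_genes, " genes")
    Y <- Y[, keep, drop = FALSE]
  }
  if (ncol(Y) == 0L) stop("no term left after the annotation filter")
  if (is.null(hidden)) hidden <- max(4L, ceiling(ncol(X) / 2))
  with_seed(seed, {
    n <- length(genes)
    tr <- sort(sample.int(n, floor(split * n)))
    te <- setdiff(seq_len(n), tr)
    mu <- colMeans(X[tr, , drop = FALSE])
    sdv <- pmax(apply(X[tr, , drop = FALSE], 2, stats::sd), 1e-8)
    Xs <- sweep(sweep(X, 2, mu), 2, sdv, `/`)
    net <- mlp_init(c(ncol(X), hidden, ncol(Y)))
    st <- adam_new(net)
    Ytr <- Y[tr, , drop = FALSE]
    for (ep in seq_len(epochs)) {
      fw <- mlp_forward(net, Xs[tr, , drop = FALSE])
      bc <- bce_with_logits(fw$out, Ytr)
      bw <- mlp_backward(net, fw, matrix(bc$grad, nrow = length(tr)))
      up <- adam_step(net, bw$grads, st, lr)
      net <- up$params; st <- up$state
    }
    sc <- mlp_forward(net, Xs[te, , drop = FALSE])$out
    rownames(sc) <- genes[te]
    colnames(sc) <- colnames(Y)
    Yte <- Y[te, , drop = FALSE]
    per_term <- do.call(rbind, lapply(seq_len(ncol(Y)), function(t) {
      yt <- Yte[, t]
      if (sum(yt) == 0 || sum(yt) == length(yt)) {
        return(data.frame(term = colnames(Y)[t], auprc = NA_real_,
                          auc = NA_real_, prevalence = mean(yt)))
      }
      data.frame(term = colnames(Y)[t],
                 auprc = average_precision(sc[, t], yt),
                 auc = roc_auc(sc[, t], yt),
                 prevalence = mean(yt))
    }))
    list(per_term = per_term, test_genes = genes[te], scores = sc)
  })
}
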