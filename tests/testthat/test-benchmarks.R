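test_that("fold plans are deterministic, balanced and shared", {
  ids <- sprintf("G%03d", 1:103)
  fp1 <- make_fold_plan(ids, folds = 5, seed = 3)
  fp2 <- make_fold_plan(ids, folds = 5, seed = 3)
  expect_identical(fp1, fp2)
  expect_false(identical(fp1, make_fold_plan(ids, folds = 5, seed = 4)))
  expect_lte(diff(range(table(fp1))), 1)
  gs <- make_fold_plan(ids, seed = 1, scheme = "gene_split",
                       test_fraction = 0.3)
  expect_equal(sum(gs == 1L), floor(0.3 * 103))
})

test_that("a leaked label column gives near-perfect gene-list auPRC", {
  w <- small_world()
  gl <- make_gene_lists(w, 1, size_range = c(25, 25), coherence = 1,
                        seed = 5)[[1]]
  leak <- random_embedding(w$universe$gene_ids, dims = 4, seed = 1)
  leak$values[, 1] <- as.numeric(rownames(leak$values) %in% gl$genes)
  r <- genelist_classify(leak, gl, seed = 1, tune_grid = NULL)
  expect_gt(mean(r$auprc), 0.95)
  expect_error(genelist_classify(leak, gene_list(gl$genes[1:3], w$universe),
                                 folds = 5, seed = 1), "smaller")
})

test_that("coherent lists on the true latent beat nulls by a wide margin", {
  w <- cached("world800", make_world(800, d_true = 8, seed = 13))
  gl <- make_gene_lists(w, 1, size_range = c(20, 20), coherence = 1,
                        seed = 6)[[1]]
  lat <- embedding_matrix(w$latent, "latent")
  fp <- make_fold_plan(w$universe$gene_ids, 5, seed = 2)
  r <- genelist_classify(lat, gl, fold_plan = fp, seed = 1, tune_grid = NULL)
  expect_gt(mean(r$auprc), 10 * r$prevalence)
  # the fold plan is reused verbatim
  expect_identical(r$fold_plan, fp)
  # novel predictions exclude the positives
  expect_false(any(r$novel %in% gl$genes))
})

test_that("elastic-net path separates a separable fixture and respects folds", {
  ids <- sprintf("G%03d", 1:80)
  with_rng(3, {
    y <- rep(c(1, 0), c(20, 60))
    X <- cbind(y * 3 + rnorm(80, sd = 0.1), rnorm(80))
    rownames(X) <- ids
  })
  uni <- gene_universe(ids)
  gl <- gene_list(ids[1:20], uni, "pos")
  emb <- embedding_matrix(X, "sep")
  fp <- make_fold_plan(ids, 4, seed = 9)
  r <- logistic_elastic_classify(emb, gl, folds = 4, fold_plan = fp, seed = 1)
  expect_gt(mean(r$auprc), 0.95)
  expect_identical(r$fold_plan, fp)
})

test_that("trait deduplication follows the Jaccard single-linkage rule", {
  uni <- gene_universe(sprintf("G%04d", 1:2500))
  mk <- function(genes, nm) gene_list(genes, uni, nm)
  # {a,b} vs {b,c}: Jaccard 1/3 > 0.3 -> same cluster
  a <- mk(sprintf("G%04d", 1:40), "a")
  b <- mk(sprintf("G%04d", 21:60), "b")   # Jaccard 20/60 = 1/3
  expect_length(dedupe_traits(list(a, b), 0.3, min_genes = 30), 1)
  # disjoint lists all retained
  d1 <- mk(sprintf("G%04d", 101:140), "d1")
  d2 <- mk(sprintf("G%04d", 201:240), "d2")
  expect_length(dedupe_traits(list(d1, d2), 0.3, 30), 2)
  # lists under the size floor are dropped
  small <- mk(sprintf("G%04d", 301:320), "small")
  expect_length(dedupe_traits(list(d1, small), 0.3, 30), 1)

  # 61 lists built to collapse into 34 clusters
  base <- lapply(1:34, function(i) {
    mk(sprintf("G%04d", (i - 1) * 70 + 1:40), sprintf("base%02d", i))
  })
  extras <- lapply(1:27, function(j) {
    src <- base[[j]]
    mk(c(src$genes[1:35], sprintf("G%04d", 2400 + j)), sprintf("dup%02d", j))
  })
  out <- dedupe_traits(c(base, extras), 0.3, 30)
  expect_length(out, 34)
  # representative is the largest list of each cluster
  expect_true(all(grepl("^base", vapply(out[1:34], function(g) g$name,
                                        character(1)))))
})

test_that("rare-variant filtering applies per-test cutoffs and the whitelist", {
  uni <- gene_universe(sprintf("G%03d", 1:200))
  tab <- data.frame(
    gene = sprintf("G%03d", c(1:40, 1:40, 41:80)),
    trait = rep(c("t1", "t2", "t3"), each = 40),
    test = c(rep("burden", 40), rep("skato", 40), rep("burden", 40)),
    p = c(rep(6.7e-7, 35), rep(1e-3, 5),       # t1: 35 at the boundary kept
          rep(2.5e-7, 40),                      # t2: all kept
          rep(1e-6, 40)),                       # t3: all above burden cutoff
    stringsAsFactors = FALSE
  )
  out <- genebass_filter(tab, uni, min_genes = 30, dedupe = FALSE)
  expect_length(out, 2)                         # t3 fails the burden cutoff
  sizes <- sort(vapply(out, function(g) length(g$genes), integer(1)))
  expect_equal(sizes, c(35, 40))
  # boundary semantics: p equal to the cutoff is retained
  one <- genebass_filter(tab[1, , drop = FALSE], uni, min_genes = 1,
                         dedupe = FALSE)
  expect_length(one, 1)
  # skato at 1e-6 is dropped
  sk <- data.frame(gene = "G001", trait = "x", test = "skato", p = 1e-6)
  expect_length(genebass_filter(sk, uni, min_genes = 1, dedupe = FALSE), 0)
  # whitelist intersection
  wl <- genebass_filter(tab, uni, whitelist = sprintf("G%03d", 1:10),
                        min_genes = 5, dedupe = FALSE)
  expect_true(all(vapply(wl, function(g) all(g$genes %in%
                                               sprintf("G%03d", 1:10)),
                         logical(1))))
  expect_error(genebass_filter(transform(sk, test = "weird"), uni), "unknown test")
  # after dedup the two overlapping traits collapse
  out2 <- genebass_filter(tab, uni, min_genes = 30, dedupe = TRUE)
  expect_length(out2, 1)
})

test_that("phenotype prediction recovers leaked labels and filters rare terms", {
  w <- small_world()
  Y <- make_phenotype_annotations(w, n_terms = 5, min_genes = 20,
                                  size_range = c(25, 35), coherence = 1)
  leak <- random_embedding(w$universe$gene_ids, dims = 2, seed = 2)
  leak$values <- cbind(leak$values, Y + 0)
  h <- hpo_multilabel(leak, Y, epochs = 150, seed = 3)
  expect_gt(median(h$per_term$auprc, na.rm = TRUE), 0.9)
  # a term below the annotation floor is dropped with a message
  Y2 <- cbind(Y, rare = c(rep(1L, 5), rep(0L, nrow(Y) - 5)))
  expect_message(h2 <- hpo_multilabel(leak, Y2, epochs = 5, seed = 3),
                 "dropping")
  expect_false("rare" %in% h2$per_term$term)
})

test_that("whitening makes block residuals independent", {
  # R = I: whitening is the identity
  y <- rnorm(8); C <- matrix(rnorm(16), 8); X <- matrix(rnorm(24), 8)
  w <- whiten(y, C, X, diag(8))
  expect_equal(w$y, y)
  expect_equal(unname(w$C), unname(C))
  # 2x2 block: whitened draws have identity covariance
  R <- matrix(c(1, 0.5, 0.5, 1), 2)
  L <- t(chol(R))
  draws <- with_rng(4, vapply(1:1e4, function(i) {
    eps <- as.numeric(L %*% rnorm(2))
    forwardsolve(L, eps)
  }, numeric(2)))
  emp <- cov(t(draws))
  expect_lt(max(abs(emp - diag(2))), 0.05)
  # round trip: L^{-1} (L y0) = y0
  y0 <- rnorm(50)
  R50 <- 0.6^abs(outer(1:50, 1:50, `-`))
  L50 <- t(chol(R50))
  expect_lt(max(abs(forwardsolve(L50, as.numeric(L50 %*% y0)) - y0)), 1e-10)
  # non-PD input gets a jitter, then fails loudly
  bad <- matrix(1, 3, 3)
  expect_message(whiten(rnorm(3), matrix(rnorm(6), 3), NULL, bad), "jitter")
})

test_that("LOCO regression needs enough chromosomes and stays calibrated", {
  w <- small_world()
  lat <- embedding_matrix(w$latent, "latent")
  sc2 <- make_gwas_scores(w, n_chromosomes = 2, seed = 1)
  expect_error(gwas_loco_fit(lat, sc2), "3 chromosomes")
  sc <- make_gwas_scores(w, h2 = 0.4, n_chromosomes = 6, seed = 2)
  g <- gwas_loco_fit(lat, sc)
  expect_gt(g$delta_r2, 0)
  expect_equal(g$delta_r2, g$r2 - g$r0_2)
  expect_equal(nrow(g$per_gene), length(sc$y))
})

test_that("publication stratification bins genes evenly and finds trends", {
  counts <- stats::setNames(seq_len(103), sprintf("G%03d", 1:103))
  per_gene <- data.frame(gene = names(counts),
                         value = with_rng(2, rnorm(103)))
  s <- publication_stratify(per_gene, counts,
                            metric_fn = function(df) mean(df$value),
                            n_bins = 5)
  expect_lte(diff(range(s$bins$n_genes)), 1)
  # publication-independent metric: no trend
  expect_gt(s$trend$p, 0.05)
  # planted increasing metric across replicates
  pg <- do.call(rbind, lapply(1:6, function(u) {
    data.frame(gene = names(counts), unit = u,
               value = counts + rnorm(103, sd = 5))
  }))
  s2 <- publication_stratify(pg, counts,
                             metric_fn = function(df) mean(df$value),
                             n_bins = 5)
  expect_gt(s2$trend$rho, 0.5)
  expect_lt(s2$trend$p, 0.01)
  expect_error(publication_stratify(data.frame(gene = "nope", value = 1),
                                    counts), "publication counts")
})
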