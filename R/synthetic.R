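# Synthetic worlds with planted gene function.
#
# A single latent space of "gene function" generates every modality the
# pipeline consumes: omics matrices (shared gene structure, dataset-specific
# samples/nonlinearity/noise/coverage), channel-scored interaction networks,
# coherent gene lists and phenotype terms, and LD-correlated gene-level GWAS
# z-scores. Publication counts are heavy-tailed and correlated with one
# latent direction, which drives every bias mechanism (biased missingness,
# literature-channel reliability, publication-biased gene lists).

# run expr under a temporary RNG state so generators are pure w.r.t. the
# caller's RNG
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Create a synthetic gene world
#'
#' Draws a ground-truth latent functional coordinate for every gene and
#' heavy-tailed per-gene publication counts. The counts are log-normal
#' (rounded up, so min >= 1) with a location term proportional to the first
#' latent direction, the designated "studiedness" axis: genes far along it
#' are the well-studied ones, emulating the strong concentration of the
#' literature on a small fraction of genes.
#'
#' @param n_genes number of genes in the universe.
#' @param d_true latent dimensionality of gene function (default 8).
#' @param seed integer seed; the world is bitwise reproducible given it.
#' @param pub_meanlog,pub_sdlog,pub_bias log-normal location/scale of
#'   publication counts and the coefficient on the studiedness axis.
#' @return object of class `synthetic_world` with `universe`, `latent`
#'   (genes x d_true, gene-id rownames), `publication_counts` (named),
#'   `studiedness`, `seed`.
#' @export
make_world <- function(n_genes, d_true = 8, seed = 1,
                       pub_meanlog = 1.5, pub_sdlog = 1.2, pub_bias = 1.2) {
  stopifnot(n_genes >= 2, d_true >= 1)
  with_seed(seed, {
    ids <- sprintf("ENSG%08d", seq_len(n_genes))
    latent <- matrix(stats::rnorm(n_genes * d_true), n_genes, d_true,
                     dimnames = list(ids, NULL))
    studied <- latent[, 1]
    pubs <- pmax(1L, as.integer(ceiling(stats::rlnorm(
      n_genes, meanlog = pub_meanlog + pub_bias * studied, sdlog = pub_sdlog))))
    names(pubs) <- ids
    structure(
      list(universe = gene_universe(ids), latent = latent,
           publication_counts = pubs, studiedness = studied, seed = seed),
      class = "synthetic_world"
    )
  })
}

#' @exportS3Method
print.synthetic_world <- function(x, ...) {
  cat("<synthetic_world> ", nrow(x$latent), " genes, latent d = ",
      ncol(x$latent), ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Collection of omics datasets sharing one gene universe
#'
#' @param datasets named list of [expression_matrix()] objects on the same
#'   universe.
#' @param universe the shared [gene_universe()].
#' @return object of class `omics_collection`.
#' @export
omics_collection <- function(datasets, universe) {
  stopifnot(length(datasets) >= 1, inherits(universe, "gene_universe"))
  if (is.null(names(datasets)) || any(names(datasets) == "")) {
    names(datasets) <- paste0("dataset", seq_along(datasets))
  }
  covered <- Reduce(`|`, lapply(datasets, function(d) d$gene_mask))
  if (!all(covered)) {
    warning(sum(!covered), " universe gene(s) present in no dataset; ",
            "they receive no embedding")
  }
  structure(list(datasets = datasets, universe = universe, covered = covered),
            class = "omics_collection")
}

#' @exportS3Method
print.omics_collection <- function(x, ...) {
  cat("<omics_collection> ", length(x$datasets), " datasets on ",
      length(x$universe), " genes\n", sep = "")
  for (nm in names(x$datasets)) {
    d <- x$datasets[[nm]]
    cat("  ", nm, ": ", nrow(d$values), " genes x ", ncol(d$values),
        " samples\n", sep = "")
  }
  invisible(x)
}

#' Generate omics matrices from a synthetic world
#'
#' Each dataset `l` is `X = f_l(latent) W' + noise` where `f_l` is a fixed
#' random nonlinearity (`tanh(gain * latent M) / gain` with a random
#' orthogonal mixing `M`; the mild gain saturates the tails while
#' preserving latent distance rank order) and `W` random sample loadings:
#' datasets share gene structure but not sample structure. Genes are dropped per the missing
#' spec; with `missing_bias = "by_publication"` low-publication genes are
#' preferentially missing, emulating the gene-inclusion biases real
#' compendia carry.
#'
#' @param world a [make_world()] world.
#' @param specs list of per-dataset specs: `name`, `n_samples`, `noise_sd`,
#'   `missing_fraction` (in \[0,1)), `missing_bias` ("none" or
#'   "by_publication").
#' @param bias_strength log-scale coefficient of the biased-missingness
#'   sampling weights (default 1.5).
#' @param nonlin_gain gain of the saturating nonlinearity (default 0.4).
#' @param seed RNG seed (default derived from the world seed).
#' @return an [omics_collection()].
#' @export
make_omics_collection <- function(world, specs, bias_strength = 1.5,
                                  nonlin_gain = 0.4,
                                  seed = world$seed + 101L) {
  stopifnot(inherits(world, "synthetic_world"), length(specs) >= 1)
  n <- nrow(world$latent)
  d <- ncol(world$latent)
  pub_z <- as.numeric(scale(log(world$publication_counts)))
  with_seed(seed, {
    datasets <- list()
    for (s in specs) {
      stopifnot(!is.null(s$n_samples))
      noise_sd <- if (is.null(s$noise_sd)) 0.1 else s$noise_sd
      mf <- if (is.null(s$missing_fraction)) 0 else s$missing_fraction
      if (mf >= 1) stop("missing_fraction must be < 1")
      bias <- if (is.null(s$missing_bias)) "none" else s$missing_bias
      M <- qr.Q(qr(matrix(stats::rnorm(d * d), d, d)))
      G <- tanh(world$latent %*% M * nonlin_gain) / nonlin_gain
      W <- matrix(stats::rnorm(s$n_samples * d), s$n_samples, d)
      X <- G %*% t(W)
      if (noise_sd > 0) X <- X + noise_sd * matrix(stats::rnorm(length(X)), n)
      rownames(X) <- world$universe$gene_ids
      colnames(X) <- paste0(s$name, "_s", seq_len(s$n_samples))
      n_miss <- floor(mf * n)
      if (n_miss > 0) {
        w <- if (bias == "by_publication") exp(-bias_strength * pub_z)
             else rep(1, n)
        drop_idx <- sample.int(n, n_miss, prob = w)
        X <- X[-drop_idx, , drop = FALSE]
      }
      datasets[[s$name]] <- suppressWarnings(
        expression_matrix(X, world$universe))
    }
    omics_collection(datasets, world$universe)
  })
}

#' Generate a channel-scored interaction network
#'
#' True edge propensity is a decreasing Gaussian kernel of latent Euclidean
#' distance; the top `density` fraction of pairs are the strong "true"
#' interactions. Each evidence channel observes *every* gene pair through a
#' noisy monotone transform on (0,1)
#' (`plogis(qlogis(propensity) + noise)`) and reports the pair only when
#' its observed evidence clears the detection limit — so a noisy channel
#' both misses true interactions and reports spurious pairs (including
#' entirely wrong ones), while an accurate channel reports exactly the
#' strong pairs. Reported scores are calibrated: the observed logit is
#' shrunk towards the detection limit by `1 / sqrt(1 + sd^2)`, so
#' unreliable channels report weak scores and reliable channels confident
#' ones, as after the benchmarking real evidence channels undergo. A pair enters the table when at least one channel reports it;
#' unreported channels are `NA` (absent evidence). All-pairs scoring keeps
#' the generator exact; it is intended for desk-scale universes (up to a
#' few thousand genes).
#'
#' When `literature_channel = TRUE` the last channel is a "literature"
#' channel with two publication-dependent distortions, both decaying
#' exponentially in `log1p(min pub) / lit_pub_scale` where `min pub` is the
#' publication count of the less-studied endpoint: a reporting *noise*
#' (starting at `lit_noise_max`) and a coverage *deficit* (a downward shift
#' of the observed evidence, starting at `lit_shift_max` logits) reflecting
#' that interactions of under-studied genes are simply not written about.
#' Interactions between well-studied genes are therefore reported almost
#' exactly; those involving under-studied genes are mostly absent from the
#' literature channel, with an occasional spurious report. What differs
#' between channels is *which* pairs they get right — the
#' annotation-inequality effect under study.
#'
#' @param world a [make_world()] world.
#' @param n_channels total number of evidence channels (default 3).
#' @param density fraction of all gene pairs that are strong interactions
#'   (default 0.05).
#' @param noise logit-scale noise standard deviation of the non-literature
#'   channels (default 1.5).
#' @param literature_channel add a publication-dependent channel named
#'   `"literature"` as the last channel?
#' @param lit_noise_max literature-channel noise at publication count 0
#'   (default 3: worse than an experimental channel).
#' @param lit_shift_max literature coverage deficit (logits) at publication
#'   count 0 (default 6: pairs of unstudied genes are essentially never
#'   reported).
#' @param lit_boost literature over-reporting of well-studied pairs
#'   (logits, default 0 = pure reliability bias): when positive,
#'   fully-studied pairs have their observed evidence raised by
#'   `lit_boost * (1 - decay)`, so the literature also reports
#'   mid-strength associations between famous genes that no experimental
#'   channel would clear — the over-annotation side of annotation
#'   inequality, used by the annotation-bias experiment.
#' @param lit_pub_scale e-folding scale of both literature distortions in
#'   `log1p(publications)` (default 1.2: noise ~0.3 and shift ~0.6 at 15
#'   publications).
#' @param report_threshold minimum observed score for a channel to report a
#'   pair; default `NULL` uses the detection limit implied by the
#'   strong-edge definition (the smallest strong-edge propensity), so a
#'   noise-free channel reports exactly the strong interactions.
#' @param prior the evidence prior re-injected into combined scores
#'   (default 0.041).
#' @param seed RNG seed (default derived from the world seed).
#' @return a [channel_edge_table()] with an extra `propensity` column
#'   (ground truth, used by tests).
#' @export
make_channel_network <- function(world, n_channels = 3, density = 0.05,
                                 noise = 1.5, literature_channel = TRUE,
                                 lit_noise_max = 3, lit_shift_max = 6,
                                 lit_boost = 0, lit_pub_scale = 1.2,
                                 report_threshold = NULL, prior = 0.041,
                                 seed = world$seed + 202L) {
  stopifnot(inherits(world, "synthetic_world"), n_channels >= 1)
  ids <- world$universe$gene_ids
  n <- length(ids)
  D <- as.matrix(stats::dist(world$latent))
  iu <- which(upper.tri(D), arr.ind = TRUE)
  dvec <- D[upper.tri(D)]
  sigma <- stats::median(dvec) / 2
  prop <- exp(-(dvec / sigma)^2)
  m <- floor(density * length(dvec))
  channel_names <- paste0("channel", seq_len(n_channels))
  if (literature_channel) channel_names[n_channels] <- "literature"
  if (m == 0L) {
    return(channel_edge_table(
      data.frame(gene_a = character(), gene_b = character()),
      channel_names = channel_names, prior = prior))
  }
  # detection limit: by default the smallest strong-edge propensity
  if (is.null(report_threshold)) report_threshold <- sort(prop, decreasing = TRUE)[m]
  with_seed(seed, {
    a <- ids[iu[, 1]]
    b <- ids[iu[, 2]]
    nc <- length(prop)
    p_edge <- pmin(pmax(prop, 1e-6), 1 - 1e-6)
    pubs <- world$publication_counts
    pub_min <- pmin(pubs[a], pubs[b])
    scores <- matrix(NA_real_, nc, n_channels,
                     dimnames = list(NULL, channel_names))
    for (c in seq_len(n_channels)) {
      if (channel_names[c] == "literature") {
        decay <- exp(-log1p(pub_min) / lit_pub_scale)
        sd_c <- lit_noise_max * decay
        shift <- lit_shift_max * decay - lit_boost * (1 - decay)
      } else {
        sd_c <- rep(noise, nc)
        shift <- 0
      }
      eps <- if (all(sd_c == 0)) 0 else stats::rnorm(nc, sd = sd_c)
      q_obs <- stats::qlogis(p_edge) - shift + eps
      # calibration: a channel's reported score is its observed evidence
      # shrunk towards the detection limit by the channel's benchmarked
      # reliability. Calibration is global per channel, as in real evidence
      # benchmarking: the experimental channels are uniformly noisy and get
      # uniformly compressed scores, while the literature channel is
      # benchmarked on the well-studied pairs that dominate it (where its
      # noise vanishes) and is therefore taken at face value -- including
      # its unreliable reports about under-studied genes. That unwarranted
      # confidence transfer is the reliability side of annotation
      # inequality.
      sd_channel <- if (channel_names[c] == "literature") 0 else noise
      q_thr <- stats::qlogis(report_threshold)
      s <- stats::plogis(q_thr + (q_obs - q_thr) / sqrt(1 + sd_channel^2))
      s[q_obs < q_thr] <- NA_real_   # below detection: not reported
      scores[, c] <- s
    }
    reported <- rowSums(!is.na(scores)) > 0
    df <- data.frame(gene_a = a[reported], gene_b = b[reported],
                     stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(scores[reported, , drop = FALSE]))
    df$propensity <- p_edge[reported]  # ground truth, kept as extra column
    channel_edge_table(df, channel_names = channel_names, prior = prior)
  })
}

# nearest-neighbour based coherent gene set around a random seed gene
.coherent_set <- function(world, size, coherence, candidates) {
  stopifnot(length(candidates) >= size)
  seed_gene <- sample(candidates, 1)
  d <- sqrt(colSums((t(world$latent[candidates, , drop = FALSE]) -
                       world$latent[seed_gene, ])^2))
  members <- candidates[order(d)][seq_len(size)]
  n_replace <- floor((1 - coherence) * size)
  if (n_replace > 0) {
    pool <- setdiff(candidates, members)
    out <- sample(members, n_replace)
    members <- c(setdiff(members, out), sample(pool, n_replace))
  }
  members
}

#' Generate coherent gene lists
#'
#' Each list is the `size` nearest neighbours of a random seed gene, with a
#' `(1 - coherence)` fraction replaced by random genes. By default
#' neighbourhoods are taken in the true latent space; when `network` is
#' given, neighbours are instead ranked by a named evidence channel's score
#' with the seed gene, emulating how curated lists are assembled *from the
#' literature* — the lists then inherit the channel's idiosyncrasies
#' (including its over-reported pairs), which is the curation circularity
#' that inflates literature-derived embeddings on such benchmarks. Genes
#' not connected to the seed in the channel are ranked behind all connected
#' ones, by latent distance.
#'
#' With `pub_biased = TRUE` candidates are restricted to genes with at
#' least `pub_floor` publications, emulating curated disease-gene lists,
#' which draw almost exclusively on well-published genes.
#'
#' @param world a [make_world()] world.
#' @param n_lists number of lists.
#' @param size_range integer range of list sizes (inclusive).
#' @param coherence fraction of each list that is true nearest neighbours
#'   (1 = pure functional module, 0 = random set).
#' @param pub_biased restrict candidates to well-published genes?
#' @param pub_floor minimum publication count of candidates when
#'   `pub_biased` (default 15).
#' @param network optional [channel_edge_table()] whose `channel` scores
#'   define the neighbourhoods (curated-from-literature mode).
#' @param channel channel name used when `network` is given (default
#'   `"literature"`).
#' @param seed RNG seed (default derived from the world seed).
#' @return list of [gene_list()] objects.
#' @export
make_gene_lists <- function(world, n_lists, size_range = c(30, 60),
                            coherence = 0.9, pub_biased = FALSE,
                            pub_floor = 15, network = NULL,
                            channel = "literature",
                            seed = world$seed + 303L) {
  stopifnot(inherits(world, "synthetic_world"))
  ids <- world$universe$gene_ids
  candidates <- if (pub_biased) {
    ids[world$publication_counts >= pub_floor]
  } else ids
  if (length(candidates) < max(size_range)) {
    stop("not enough candidate genes for the requested list size")
  }
  rank_fn <- NULL
  if (!is.null(network)) {
    stopifnot(inherits(network, "channel_edge_table"),
              channel %in% attr(network, "channel_names"))
    df <- as.data.frame(network)
    df <- df[!is.na(df[[channel]]), c("gene_a", "gene_b", channel)]
    rank_fn <- function(seed_gene) {
      sc <- stats::setNames(rep(0, length(candidates)), candidates)
      hit <- df$gene_a == seed_gene | df$gene_b == seed_gene
      other <- ifelse(df$gene_a[hit] == seed_gene, df$gene_b[hit],
                      df$gene_a[hit])
      keep <- other %in% candidates
      sc[other[keep]] <- df[[channel]][hit][keep]
      # connected genes first (by score), then the rest by latent distance
      d <- sqrt(colSums((t(world$latent[candidates, , drop = FALSE]) -
                           world$latent[seed_gene, ])^2))
      candidates[order(-sc, d)]
    }
  }
  with_seed(seed, {
    lapply(seq_len(n_lists), function(i) {
      size <- if (size_range[1] == size_range[2]) size_range[1] else
        sample(size_range[1]:size_range[2], 1)
      members <- if (is.null(rank_fn)) {
        .coherent_set(world, size, coherence, candidates)
      } else {
        seed_gene <- sample(candidates, 1)
        m <- rank_fn(seed_gene)[seq_len(size)]
        n_replace <- floor((1 - coherence) * size)
        if (n_replace > 0) {
          out <- sample(m, n_replace)
          m <- c(setdiff(m, out), sample(setdiff(candidates, m), n_replace))
        }
        m
      }
      gene_list(members, world$universe,
                name = sprintf("list%02d", i),
                source_tag = if (!is.null(rank_fn)) "synthetic:from_network"
                             else if (pub_biased) "synthetic:pub_biased"
                             else "synthetic")
    })
  })
}

#' Generate gene-level GWAS z-scores with LD-structured residuals
#'
#' Implements the generative model `y = C alpha + g + eps`,
#' `eps ~ MVN(0, R)`: six covariates (three positive gene-level quantities
#' emulating gene density, effective gene size and inverse mean minor-allele
#' count, plus their logs), a latent functional signal `g` carrying a
#' fraction `h2` of the non-covariate variance, and residuals correlated
#' within LD blocks. Genes are assigned to chromosomes round-robin so
#' leave-one-chromosome-out folds are balanced; within a chromosome the
#' residual covariance is block-diagonal with AR(1) blocks
#' `R[i,j] = rho^|i-j|` of size `ld_block_size`.
#'
#' @param world a [make_world()] world.
#' @param effect_embedding optional [embedding_matrix()] whose (random
#'   linear) projection is the true signal; default uses the world latent.
#' @param n_chromosomes number of chromosomes (default 22).
#' @param ld_block_size LD block size (1 = independent residuals).
#' @param h2 variance share of the latent signal among signal + residual,
#'   in \[0, 1\].
#' @param rho AR(1) within-block correlation, |rho| < 1 (default 0.5).
#' @param alpha optional fixed covariate coefficient vector (length 6);
#'   default draws one per trait.
#' @param studiedness_free draw the trait effect orthogonal to the
#'   studiedness latent axis (default TRUE)? This makes the z-scores an
#'   annotation-unbiased benchmark: per-gene signal magnitude is
#'   independent of publication count, so any publication gradient in
#'   downstream performance reflects the embedding, not the trait.
#' @param seed RNG seed; pass different seeds for replicate traits.
#' @return object of class `gwas_gene_scores` with `y`, `C`, `chromosome`,
#'   `R_blocks` (one covariance matrix per chromosome), `gene_ids`.
#' @export
make_gwas_scores <- function(world, effect_embedding = NULL,
                             n_chromosomes = 22, ld_block_size = 10,
                             h2 = 0.3, rho = 0.5, alpha = NULL,
                             studiedness_free = TRUE,
                             seed = world$seed + 404L) {
  stopifnot(inherits(world, "synthetic_world"),
            h2 >= 0, h2 <= 1, n_chromosomes >= 1)
  if (abs(rho) >= 1) stop("|rho| >= 1 gives a non-positive-definite LD block")
  ids <- world$universe$gene_ids
  n <- length(ids)
  chrom <- ((seq_len(n) - 1L) %% n_chromosomes) + 1L
  names(chrom) <- ids
  # covariates are gene properties: fixed per world, shared across traits
  C <- with_seed(world$seed + 909L, {
    b1 <- stats::rlnorm(n, 0, 0.5)          # gene density
    b2 <- stats::rlnorm(n, 1, 0.7)          # effective gene size
    b3 <- stats::rlnorm(n, -1, 0.5)         # inverse mean MAC
    out <- cbind(b1, b2, b3, log(b1), log(b2), log(b3))
    colnames(out) <- c("density", "size", "inv_mac",
                       "log_density", "log_size", "log_inv_mac")
    rownames(out) <- ids
    out
  })
  with_seed(seed, {
    if (is.null(alpha)) alpha <- stats::rnorm(6, sd = 0.3)
    stopifnot(length(alpha) == ncol(C))
    cov_part <- as.numeric(C %*% alpha)
    sd_cov <- stats::sd(cov_part)
    cov_part <- if (sd_cov > 0) (cov_part - mean(cov_part)) / sd_cov else
      rep(0, n)
    E <- if (is.null(effect_embedding)) world$latent else {
      stopifnot(inherits(effect_embedding, "embedding_matrix"))
      effect_embedding$values[ids, , drop = FALSE]
    }
    u <- stats::rnorm(ncol(E))
    if (studiedness_free && is.null(effect_embedding) && length(u) > 1) {
      u[1] <- 0   # no effect along the studiedness axis
    }
    g <- as.numeric(E %*% u)
    g <- if (h2 > 0) (g - mean(g)) / stats::sd(g) * sqrt(h2) else rep(0, n)
    R_blocks <- list()
    eps <- numeric(n)
    for (ch in seq_len(n_chromosomes)) {
      idx <- which(chrom == ch)
      nch <- length(idx)
      R <- matrix(0, nch, nch)
      starts <- seq(1, nch, by = ld_block_size)
      for (s in starts) {
        e <- min(s + ld_block_size - 1L, nch)
        blk <- s:e
        R[blk, blk] <- rho^abs(outer(blk, blk, `-`))
      }
      dimnames(R) <- list(ids[idx], ids[idx])
      R_blocks[[as.character(ch)]] <- R
      L <- t(chol(R))
      eps[idx] <- sqrt(1 - h2) * as.numeric(L %*% stats::rnorm(nch))
    }
    y <- cov_part + g + eps
    names(y) <- ids
    structure(
      list(y = y, C = C, chromosome = chrom, R_blocks = R_blocks,
           gene_ids = ids, h2 = h2),
      class = "gwas_gene_scores"
    )
  })
}

#' @exportS3Method
print.gwas_gene_scores <- function(x, ...) {
  cat("<gwas_gene_scores> ", length(x$y), " genes on ",
      length(x$R_blocks), " chromosomes (h2 = ", x$h2, ")\n", sep = "")
  invisible(x)
}

#' Generate a multi-hot phenotype annotation matrix
#'
#' Each phenotype term is a coherent gene set (as in [make_gene_lists()]);
#' term sizes are drawn from `size_range` and are never below `min_genes`,
#' matching the usual practice of keeping only terms with a workable number
#' of annotated genes.
#'
#' @param world a [make_world()] world.
#' @param n_terms number of phenotype terms.
#' @param min_genes minimum genes per term (default 20).
#' @param size_range term size range; lower bound raised to `min_genes`.
#' @param coherence as in [make_gene_lists()].
#' @param seed RNG seed (default derived from the world seed).
#' @return binary matrix genes x terms with gene-id rownames.
#' @export
make_phenotype_annotations <- function(world, n_terms, min_genes = 20,
                                       size_range = c(20, 40),
                                       coherence = 0.9,
                                       seed = world$seed + 505L) {
  stopifnot(inherits(world, "synthetic_world"), n_terms >= 1)
  size_range[1] <- max(size_range[1], min_genes)
  size_range[2] <- max(size_range[2], size_range[1])
  ids <- world$universe$gene_ids
  with_seed(seed, {
    Y <- matrix(0L, length(ids), n_terms,
                dimnames = list(ids, sprintf("term%03d", seq_len(n_terms))))
    for (t in seq_len(n_terms)) {
      repeat {
        size <- if (size_range[1] == size_range[2]) size_range[1] else
          sample(size_range[1]:size_range[2], 1)
        members <- .coherent_set(world, size, coherence, ids)
        if (length(members) >= min_genes) break
      }
      Y[members, t] <- 1L
    }
    Y
  })
}
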