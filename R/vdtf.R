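#' Closed-form KL divergence between univariate Gaussians
#'
#' `KL(N(mean, var) || N(prior_mean, prior_var))`, vectorised elementwise;
#' callers sum over genes and dimensions.
#'
#' @param mean,var posterior mean and variance (`var > 0`).
#' @param prior_mean,prior_var prior mean and variance (defaults 0, 1).
#' @return elementwise KL values (same shape as the inputs).
#' @export
gaussian_kl <- function(mean, var, prior_mean = 0, prior_var = 1) {
  if (any(var <= 0) || any(prior_var <= 0)) stop("variances must be positive")
  0.5 * (log(prior_var / var) + (var + (mean - prior_mean)^2) / prior_var - 1)
}

#' Gradient reversal
#'
#' The domain-adaptation primitive: the forward pass is the identity and the
#' backward pass multiplies the incoming gradient by `-lambda`. Because the
#' package's backpropagation is explicit, the two directions are two
#' functions: [gradient_reversal()] (forward) and [grl_backward()]
#' (backward), composed inside the training loop between the shared gene
#' embedding and the domain classifier.
#'
#' @param x forward input (returned unchanged).
#' @param lambda reversal strength (recorded as an attribute).
#' @return `x`, with attribute `grl_lambda`.
#' @export
gradient_reversal <- function(x, lambda = 1) {
  attr(x, "grl_lambda") <- lambda
  x
}

#' @rdname gradient_reversal
#' @param grad gradient arriving from the domain classifier.
#' @return `-lambda * grad`.
#' @export
grl_backward <- function(grad, lambda = 1) -lambda * grad

#' Learning-rate scaling for blockwise training
#'
#' Datasets with many batches would otherwise dominate the shared embedding
#' updates; the embedding-layer learning rate within each dataset's block is
#' the global rate divided by the square root of that dataset's number of
#' batches.
#'
#' @param global_lr the global learning rate.
#' @param n_batches batches per epoch for the dataset.
#' @return the scaled embedding learning rate.
#' @export
scaled_lr <- function(global_lr, n_batches) {
  stopifnot(n_batches >= 1)
  global_lr / sqrt(n_batches)
}

#' Variational deep tensor factorization of an omics collection
#'
#' Learns one shared gene embedding from multiple genes-by-samples matrices
#' with dataset-specific gene coverage. Each dataset `l` reconstructs its
#' entries as `xhat_ij = f_l(a_i^(l), b_j^(l))`: a dataset-specific
#' three-layer leaky-ReLU network applied to the concatenation of a sampled
#' dataset-specific gene embedding and a sample embedding. The gene
#' embedding is variational: `a_ik^(l) ~ N(a_ik, sigma2_ik + v_ik^(l))`,
#' with a shared mean `A`, a common variance `Sigma2` regularised towards
#' `N(0, 1)` and a dataset-specific variance `V^(l)` regularised towards a
#' scalar prior `v_prior^(l)`. The per-dataset prior variances are the
#' model's hyperparameters: they set the relative influence of each dataset
#' on the shared embedding (see [tune_v_priors()]).
#'
#' Training is blockwise: each epoch iterates over datasets; a dataset's
#' block updates its sample embeddings and reconstruction network, the
#' shared `A`/`Sigma2`/`V^(l)`, and a two-layer domain classifier whose
#' binary cross-entropy loss (predicting per-gene dataset membership) is
#' added to the objective through a gradient reversal layer, so the
#' embedding is optimised to *not* encode which datasets cover a gene.
#' Sample embeddings are initialised from principal components of their
#' dataset; everything else starts random from `seed`. Adam is used
#' throughout, with the embedding-layer learning rate scaled per dataset by
#' [scaled_lr()]. The loss over observed cells is mean squared error
#' (missing cells are simply not summed over); KL terms are scaled per
#' observed training cell (see the methods vignette) and multiplied by
#' `kl_weight`. A best-validation checkpoint over the fixed epoch budget is
#' returned.
#'
#' @param collection an [omics_collection()].
#' @param v_priors numeric vector of per-dataset prior variances (default
#'   0.1 for each dataset; larger values loosen a dataset's coupling to the
#'   shared embedding and add more sampling noise to its draws).
#' @param K shared embedding dimension (default 256, the published
#'   configuration; reduce for small universes).
#' @param sample_dims per-dataset sample-embedding dimensions; default
#'   `min(K, n_samples - 1)` per dataset (the published three-dataset
#'   configuration used 256/128/64).
#' @param hidden hidden width of the reconstruction networks (default `K`).
#' @param epochs fixed epoch budget.
#' @param batch_size samples per batch (default 64).
#' @param global_lr global Adam learning rate.
#' @param val_fraction fraction of observed cells held out for validation.
#' @param grl_weight gradient-reversal strength lambda (0 disables the
#'   adversarial signal to the embedding; the classifier still trains).
#' @param domain_weight weight of the domain-classifier loss.
#' @param kl_weight weight of the KL terms.
#' @param var_floor numerical floor added to all variances.
#' @param slope leaky-ReLU negative slope.
#' @param linear disable activations (closed-form test mode).
#' @param seed RNG seed; fits are bitwise reproducible given it.
#' @param verbose print per-epoch losses?
#' @return an object of class `vdtf`; see [coef.vdtf()], [predict.vdtf()],
#'   [plot.vdtf()].
#' @export
vdtf <- function(collection, v_priors = NULL, K = 256, sample_dims = NULL,
                 hidden = K, epochs = 50, batch_size = 64, global_lr = 0.01,
                 val_fraction = 0.1, grl_weight = 1, domain_weight = 1,
                 kl_weight = 1, var_floor = 1e-6, slope = 0.01,
                 linear = FALSE, seed = 1, verbose = FALSE) {
  stopifnot(inherits(collection, "omics_collection"),
            val_fraction > 0, val_fraction < 1, epochs >= 1)
  L <- length(collection$datasets)
  dnames <- names(collection$datasets)
  if (is.null(v_priors)) v_priors <- rep(0.1, L)
  stopifnot(length(v_priors) == L, all(v_priors > 0))

  genes <- collection$universe$gene_ids[collection$covered]
  n_g <- length(genes)
  gene_pos <- stats::setNames(seq_len(n_g), genes)

  with_seed(seed, {
    A <- matrix(stats::rnorm(n_g * K, sd = 0.1), n_g, K,
                dimnames = list(genes, NULL))
    logs2 <- matrix(log(0.1), n_g, K)
    Mem <- vapply(collection$datasets,
                  function(d) as.numeric(genes %in% rownames(d$values)),
                  numeric(n_g))
    dom <- mlp_init(c(K, max(4L, ceiling(K / 2)), L))

    ds <- vector("list", L)
    names(ds) <- dnames
    for (l in seq_len(L)) {
      X <- collection$datasets[[l]]$values
      G <- nrow(X); S <- ncol(X)
      Kl <- if (is.null(sample_dims)) min(K, S - 1L) else sample_dims[l]
      obs <- is.finite(X)
      cells <- which(obs)
      val <- sample(cells, max(1L, floor(val_fraction * length(cells))))
      trainmask <- obs
      trainmask[val] <- FALSE
      # sample embeddings from principal components of the dataset
      Xc <- X; Xc[!obs] <- 0
      Xc <- sweep(Xc, 1, rowMeans(Xc))
      sv <- svd(Xc, nu = 0, nv = min(Kl, min(G, S)))
      B <- matrix(stats::rnorm(S * Kl, sd = 0.1), S, Kl)
      kk <- ncol(sv$v)
      B[, seq_len(kk)] <- sweep(sv$v[, seq_len(kk), drop = FALSE], 2,
                                pmax(apply(sv$v[, seq_len(kk), drop = FALSE],
                                           2, stats::sd), 1e-12), `/`)
      ds[[l]] <- list(
        name = dnames[l], X = X, obs = obs, trainmask = trainmask,
        valmask = obs & !trainmask,
        gidx = unname(gene_pos[rownames(X)]), Kl = Kl, B = B,
        f = mlp_init(c(K + Kl, hidden, hidden, 1)),
        logv = matrix(log(v_priors[l]), G, K),
        v_prior = v_priors[l],
        n_train = sum(trainmask),
        n_batches = max(1L, ceiling(S / batch_size))
      )
    }

    opt <- list(
      A = adam_new(A), logs2 = adam_new(logs2), dom = adam_new(dom),
      ds = lapply(ds, function(d) list(B = adam_new(d$B), f = adam_new(d$f),
                                       logv = adam_new(d$logv)))
    )

    log_df <- data.frame()
    best <- list(val = Inf)

    for (ep in seq_len(epochs)) {
      ep_comp <- c(recon = 0, kl_a = 0, kl_v = 0, dom = 0)
      n_blocks <- 0
      for (l in seq_len(L)) {
        d <- ds[[l]]
        lr_emb <- scaled_lr(global_lr, d$n_batches)
        S <- ncol(d$X)
        order_s <- sample.int(S)
        batches <- split(order_s, ceiling(seq_along(order_s) / batch_size))
        for (bt in batches) {
          G <- nrow(d$X)
          gi <- rep(seq_len(G), times = length(bt))
          si <- rep(bt, each = G)
          eps <- matrix(stats::rnorm(G * K), G, K)
          s2 <- var_floor + exp(logs2[d$gidx, , drop = FALSE])
          vl <- var_floor + exp(d$logv)
          sdv <- sqrt(s2 + vl)
          Ag <- A[d$gidx, , drop = FALSE]
          a_l <- Ag + sdv * eps
          IN <- cbind(a_l[gi, , drop = FALSE], d$B[si, , drop = FALSE])
          fw <- mlp_forward(d$f, IN, slope, linear)
          xb <- as.vector(d$X[, bt, drop = FALSE])
          mb <- as.vector(d$trainmask[, bt, drop = FALSE])
          nob <- sum(mb)
          if (nob == 0L) next
          resid <- fw$out[, 1] - xb
          recon <- sum(resid[mb]^2) / nob
          dxhat <- numeric(length(xb))
          dxhat[mb] <- 2 * resid[mb] / nob
          bw <- mlp_backward(d$f, fw, matrix(dxhat, ncol = 1), slope, linear)
          dIN <- bw$dX
          dA_l <- rowsum(dIN[, seq_len(K), drop = FALSE], gi)
          dB_small <- rowsum(dIN[, K + seq_len(d$Kl), drop = FALSE], si)
          dB <- d$B * 0
          dB[as.integer(rownames(dB_small)), ] <- dB_small

          kw <- kl_weight / d$n_train
          kl_a_el <- gaussian_kl(Ag, s2)
          kl_a <- kw * sum(kl_a_el)
          kl_v_el <- gaussian_kl(0 * vl, vl, 0, d$v_prior)
          kl_v <- kw * sum(kl_v_el)

          ds2 <- dA_l * eps / (2 * sdv)
          dA_g <- dA_l + kw * Ag
          dlogs2_g <- (ds2 + kw * 0.5 * (1 - 1 / s2)) *
            exp(logs2[d$gidx, , drop = FALSE])
          dlogv <- (ds2 + kw * 0.5 * (1 / d$v_prior - 1 / vl)) * exp(d$logv)

          # domain classifier on the full embedding, adversarial through GRL;
          # weight decay keeps the classifier from saturating (a saturated
          # classifier has vanishing gradients and the reversal does nothing)
          dfw <- mlp_forward(dom, A, slope)
          dbce <- bce_with_logits(dfw$out, Mem)
          dom_loss <- dbce$loss
          dbw <- mlp_backward(dom, dfw, domain_weight * dbce$grad, slope)
          dbw$grads <- .map_leaves(function(g, p) g + 1e-2 * p,
                                   dbw$grads, dom)

          total <- recon + kl_a + kl_v + domain_weight * dom_loss
          if (!is.finite(total)) {
            stop("vdtf diverged at epoch ", ep, " (dataset ", d$name,
                 "): recon=", signif(recon, 4), " kl_a=", signif(kl_a, 4),
                 " kl_v=", signif(kl_v, 4), " dom=", signif(dom_loss, 4))
          }

          gA <- matrix(0, n_g, K)
          gA[d$gidx, ] <- dA_g
          gA <- gA + grl_backward(dbw$dX, grl_weight)
          glogs2 <- matrix(0, n_g, K)
          glogs2[d$gidx, ] <- dlogs2_g

          st <- adam_step(A, gA, opt$A, lr_emb)
          A <- st$params; opt$A <- st$state
          st <- adam_step(logs2, glogs2, opt$logs2, lr_emb)
          logs2 <- st$params; opt$logs2 <- st$state
          st <- adam_step(d$logv, dlogv, opt$ds[[l]]$logv, lr_emb)
          d$logv <- st$params; opt$ds[[l]]$logv <- st$state
          st <- adam_step(d$B, dB, opt$ds[[l]]$B, lr_emb)
          d$B <- st$params; opt$ds[[l]]$B <- st$state
          st <- adam_step(d$f, bw$grads, opt$ds[[l]]$f, global_lr)
          d$f <- st$params; opt$ds[[l]]$f <- st$state
          st <- adam_step(dom, dbw$grads, opt$dom, global_lr)
          dom <- st$params; opt$dom <- st$state

          ep_comp <- ep_comp + c(recon, kl_a, kl_v, dom_loss)
          n_blocks <- n_blocks + 1
        }
        ds[[l]] <- d
      }
      ep_comp <- ep_comp / n_blocks

      # validation: posterior-mean reconstruction on held-out cells
      val_sse <- 0; val_n <- 0
      for (l in seq_len(L)) {
        d <- ds[[l]]
        vm <- d$valmask
        if (!any(vm)) next
        pred <- .vdtf_reconstruct_matrix(A, d, slope, linear)
        val_sse <- val_sse + sum((pred - d$X)[vm]^2)
        val_n <- val_n + sum(vm)
      }
      val_mse <- val_sse / max(val_n, 1)
      log_df <- rbind(log_df, data.frame(
        epoch = ep, train_recon = ep_comp[["recon"]],
        kl_embedding = ep_comp[["kl_a"]], kl_dataset_var = ep_comp[["kl_v"]],
        domain = ep_comp[["dom"]], val_mse = val_mse))
      if (verbose) {
        message(sprintf("epoch %3d  recon %.4f  kl_a %.4f  kl_v %.4f  dom %.4f  val %.4f",
                        ep, ep_comp[["recon"]], ep_comp[["kl_a"]],
                        ep_comp[["kl_v"]], ep_comp[["dom"]], val_mse))
      }
      if (val_mse < best$val) {
        best <- list(val = val_mse, epoch = ep, A = A, logs2 = logs2,
                     dom = dom,
                     ds_state = lapply(ds, function(d)
                       list(B = d$B, f = d$f, logv = d$logv)))
      }
    }

    # restore the best-validation checkpoint
    A <- best$A; logs2 <- best$logs2; dom <- best$dom
    for (l in seq_len(L)) {
      ds[[l]]$B <- best$ds_state[[l]]$B
      ds[[l]]$f <- best$ds_state[[l]]$f
      ds[[l]]$logv <- best$ds_state[[l]]$logv
    }

    structure(list(
      A = A, logs2 = logs2, dom = dom, datasets = ds, genes = genes,
      membership = Mem, v_priors = stats::setNames(v_priors, dnames),
      K = K, log = log_df, best_epoch = best$epoch, best_val = best$val,
      config = list(hidden = hidden, epochs = epochs, batch_size = batch_size,
                    global_lr = global_lr, val_fraction = val_fraction,
                    grl_weight = grl_weight, domain_weight = domain_weight,
                    kl_weight = kl_weight, var_floor = var_floor,
                    slope = slope, linear = linear, seed = seed)
    ), class = "vdtf")
  })
}

# posterior-mean reconstruction of a full dataset matrix
.vdtf_reconstruct_matrix <- function(A, d, slope, linear) {
  G <- nrow(d$X); S <- ncol(d$X)
  gi <- rep(seq_len(G), times = S)
  si <- rep(seq_len(S), each = G)
  IN <- cbind(A[d$gidx, , drop = FALSE][gi, , drop = FALSE],
              d$B[si, , drop = FALSE])
  matrix(mlp_forward(d$f, IN, slope, linear)$out, G, S,
         dimnames = dimnames(d$X))
}

#' @exportS3Method
print.vdtf <- function(x, ...) {
  cat("Variational deep tensor factorization\n")
  cat("  genes:", length(x$genes), " embedding dims:", x$K, "\n")
  cat("  datasets:", paste(names(x$datasets), collapse = ", "), "\n")
  cat("  v_priors:", paste(signif(x$v_priors, 3), collapse = ", "), "\n")
  cat("  best validation MSE", signif(x$best_val, 4),
      "at epoch", x$best_epoch, "of", x$config$epochs, "\n")
  invisible(x)
}

#' @exportS3Method
summary.vdtf <- function(object, ...) {
  s2 <- object$config$var_floor + exp(object$logs2)
  cat("Variational deep tensor factorization\n\n")
  print(object)
  cat("\n  mean common posterior variance:", signif(mean(s2), 4), "\n")
  for (nm in names(object$datasets)) {
    d <- object$datasets[[nm]]
    vl <- object$config$var_floor + exp(d$logv)
    cat("  ", nm, ": ", nrow(d$X), " genes x ", ncol(d$X),
        " samples, mean v = ", signif(mean(vl), 4),
        " (prior ", d$v_prior, ")\n", sep = "")
  }
  invisible(object)
}

#' Extract the shared gene embedding
#'
#' @param object a fitted [vdtf()] model.
#' @param ... unused.
#' @return the genes x K matrix of shared embedding means.
#' @export
coef.vdtf <- function(object, ...) object$A

#' The fitted embedding as an [embedding_matrix()]
#' @param model a fitted [vdtf()] model.
#' @export
as_embedding <- function(model) {
  stopifnot(inherits(model, "vdtf"))
  embedding_matrix(model$A, provenance = "omics_vdtf")
}

#' Reconstruct dataset entries from a fitted model
#'
#' @param object a fitted [vdtf()] model.
#' @param dataset dataset name.
#' @param ... unused.
#' @return the posterior-mean reconstruction matrix (genes x samples of the
#'   dataset).
#' @export
predict.vdtf <- function(object, dataset = names(object$datasets)[1], ...) {
  d <- object$datasets[[dataset]]
  if (is.null(d)) stop("unknown dataset: ", dataset)
  .vdtf_reconstruct_matrix(object$A, d, object$config$slope,
                           object$config$linear)
}

#' @export
residuals.vdtf <- function(object, ...) {
  lapply(stats::setNames(nm = names(object$datasets)), function(nm) {
    r <- object$datasets[[nm]]$X - predict(object, nm)
    r[!object$datasets[[nm]]$obs] <- NA
    r
  })
}

#' @export
fitted.vdtf <- function(object, ...) {
  lapply(stats::setNames(nm = names(object$datasets)),
         function(nm) predict(object, nm))
}

#' Simulate reconstructions with sampled dataset-specific embeddings
#'
#' Each replicate draws `a^(l) ~ N(A, Sigma2 + V^(l))` and reconstructs the
#' dataset, giving the model's predictive spread.
#'
#' @param object a fitted [vdtf()] model.
#' @param nsim replicates.
#' @param seed RNG seed.
#' @param dataset dataset name.
#' @param ... unused.
#' @return list of `nsim` reconstruction matrices.
#' @export
simulate.vdtf <- function(object, nsim = 1, seed = 1,
                          dataset = names(object$datasets)[1], ...) {
  d <- object$datasets[[dataset]]
  if (is.null(d)) stop("unknown dataset: ", dataset)
  cfg <- object$config
  with_seed(seed, {
    lapply(seq_len(nsim), function(i) {
      G <- nrow(d$X)
      s2 <- cfg$var_floor + exp(object$logs2[d$gidx, , drop = FALSE])
      vl <- cfg$var_floor + exp(d$logv)
      a_l <- object$A[d$gidx, , drop = FALSE] +
        sqrt(s2 + vl) * matrix(stats::rnorm(G * object$K), G)
      dd <- d
      Atmp <- object$A
      Atmp[d$gidx, ] <- a_l
      .vdtf_reconstruct_matrix(Atmp, dd, cfg$slope, cfg$linear)
    })
  })
}

#' @export
plot.vdtf <- function(x, ...) {
  graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(mfrow = c(1, 1)))
  with(x$log, {
    graphics::plot(epoch, train_recon, type = "l", xlab = "epoch",
                   ylab = "training reconstruction MSE", ...)
    graphics::plot(epoch, val_mse, type = "l", xlab = "epoch",
                   ylab = "validation MSE", ...)
    graphics::abline(v = x$best_epoch, lty = 2)
  })
  invisible(x)
}

#' Reconstruct a single dataset entry
#'
#' Applies the dataset's reconstruction network to the concatenation of a
#' gene embedding and a sample embedding. Genes outside the dataset's mask
#' are never reconstructed (error).
#'
#' @param model a fitted [vdtf()] model.
#' @param dataset dataset name.
#' @param gene gene id.
#' @param sample sample index or id.
#' @param a optional sampled dataset-specific gene embedding (defaults to
#'   the posterior mean).
#' @return the predicted value.
#' @export
reconstruct <- function(model, dataset, gene, sample, a = NULL) {
  stopifnot(inherits(model, "vdtf"))
  d <- model$datasets[[dataset]]
  if (is.null(d)) stop("unknown dataset: ", dataset)
  gi <- match(gene, rownames(d$X))
  if (is.na(gi)) stop("gene ", gene, " is not present in dataset ", dataset)
  si <- if (is.character(sample)) match(sample, colnames(d$X)) else sample
  if (is.na(si) || si < 1 || si > ncol(d$X)) stop("unknown sample: ", sample)
  if (is.null(a)) a <- model$A[d$gidx[gi], ]
  IN <- matrix(c(a, d$B[si, ]), nrow = 1)
  mlp_forward(d$f, IN, model$config$slope, model$config$linear)$out[1, 1]
}

#' Draw a dataset-specific gene embedding
#'
#' Reparameterised draw `a + sqrt(sigma2 + v^(l)) * xi`, `xi ~ N(0, 1)`.
#'
#' @param model a fitted [vdtf()] model.
#' @param dataset dataset name.
#' @param gene gene id.
#' @param seed optional seed for a reproducible draw.
#' @return numeric vector of length `K`.
#' @export
sample_dataset_embedding <- function(model, dataset, gene, seed = NULL) {
  stopifnot(inherits(model, "vdtf"))
  d <- model$datasets[[dataset]]
  if (is.null(d)) stop("unknown dataset: ", dataset)
  gi <- match(gene, rownames(d$X))
  if (is.na(gi)) stop("gene ", gene, " is not present in dataset ", dataset)
  cfg <- model$config
  s2 <- cfg$var_floor + exp(model$logs2[d$gidx[gi], ])
  vl <- cfg$var_floor + exp(d$logv[gi, ])
  draw <- function() model$A[d$gidx[gi], ] +
    sqrt(s2 + vl) * stats::rnorm(model$K)
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Evidence-lower-bound components for one dataset batch
#'
#' Recomputes the training objective on a batch of samples from one dataset:
#' the mean-squared reconstruction error over observed cells, the KL of the
#' common embedding against `N(0, 1)` and the KL of the dataset variance
#' against its prior (both scaled as during training), and their total.
#'
#' @param model a fitted [vdtf()] model.
#' @param dataset dataset name.
#' @param samples sample indices (default all).
#' @param seed seed for the variational draw.
#' @return list with `total`, `reconstruction`, `kl_embedding`,
#'   `kl_dataset_var`.
#' @export
elbo_loss <- function(model, dataset, samples = NULL, seed = 1) {
  stopifnot(inherits(model, "vdtf"))
  d <- model$datasets[[dataset]]
  if (is.null(d)) stop("unknown dataset: ", dataset)
  cfg <- model$config
  if (is.null(samples)) samples <- seq_len(ncol(d$X))
  mb <- as.vector(d$obs[, samples, drop = FALSE])
  if (!any(mb)) stop("batch has zero observed entries")
  with_seed(seed, {
    G <- nrow(d$X)
    s2 <- cfg$var_floor + exp(model$logs2[d$gidx, , drop = FALSE])
    vl <- cfg$var_floor + exp(d$logv)
    a_l <- model$A[d$gidx, , drop = FALSE] +
      sqrt(s2 + vl) * matrix(stats::rnorm(G * model$K), G)
    gi <- rep(seq_len(G), times = length(samples))
    si <- rep(samples, each = G)
    IN <- cbind(a_l[gi, , drop = FALSE], d$B[si, , drop = FALSE])
    xhat <- mlp_forward(d$f, IN, cfg$slope, cfg$linear)$out[, 1]
    xb <- as.vector(d$X[, samples, drop = FALSE])
    recon <- sum((xhat - xb)[mb]^2) / sum(mb)
    kw <- cfg$kl_weight / d$n_train
    kl_a <- kw * sum(gaussian_kl(model$A[d$gidx, , drop = FALSE], s2))
    kl_v <- kw * sum(gaussian_kl(0 * vl, vl, 0, d$v_prior))
    list(total = recon + kl_a + kl_v, reconstruction = recon,
         kl_embedding = kl_a, kl_dataset_var = kl_v)
  })
}

#' Probe how much dataset-membership information the embedding carries
#'
#' Trains a fresh two-layer classifier on the frozen shared embedding to
#' predict per-gene dataset membership, with a 70/30 gene split, and
#' returns the held-out accuracy. This is the diagnostic for the gradient
#' reversal layer: an embedding trained with an active GRL should carry
#' less membership information, i.e. a lower probe accuracy, than one
#' trained with the reversal disabled.
#'
#' The accuracy of a single 70/30 split carries sampling noise of the same
#' order as the reversal effect on small universes; `reps > 1` averages the
#' probe over independent splits and initialisations.
#'
#' @param model a fitted [vdtf()] model.
#' @param split train fraction (default 0.7).
#' @param epochs probe training epochs (default 300, full batch Adam).
#' @param lr probe learning rate.
#' @param seed RNG seed for the split and probe initialisation.
#' @param reps number of independent probes averaged (default 1).
#' @return held-out accuracy in \[0, 1\] (elementwise over genes and
#'   datasets), averaged over `reps` probes.
#' @export
domain_probe_accuracy <- function(model, split = 0.7, epochs = 300,
                                  lr = 0.01, seed = 1, reps = 1) {
  stopifnot(inherits(model, "vdtf"))
  if (reps > 1) {
    return(mean(vapply(seq_len(reps), function(r) {
      domain_probe_accuracy(model, split, epochs, lr, seed = seed + r - 1L)
    }, numeric(1))))
  }
  A <- model$A
  Mem <- model$membership
  with_seed(seed, {
    n <- nrow(A)
    tr <- sort(sample.int(n, floor(split * n)))
    te <- setdiff(seq_len(n), tr)
    net <- mlp_init(c(ncol(A), max(4L, ncol(A)), ncol(Mem)))
    st <- adam_new(net)
    for (ep in seq_len(epochs)) {
      fw <- mlp_forward(net, A[tr, , drop = FALSE])
      bc <- bce_with_logits(fw$out, Mem[tr, , drop = FALSE])
      bw <- mlp_backward(net, fw, matrix(bc$grad, nrow = length(tr)))
      up <- adam_step(net, bw$grads, st, lr)
      net <- up$params; st <- up$state
    }
    pred <- mlp_forward(net, A[te, , drop = FALSE])$out > 0
    mean(pred == (Mem[te, , drop = FALSE] > 0.5))
  })
}

#' Grid search over the per-dataset prior variances
#'
#' Fits the model for every candidate vector of prior variances (a reduced
#' epoch budget is standard here) and scores each fit by the average
#' precision of recalling high-confidence network edges when ranking gene
#' pairs by embedding Euclidean distance; returns the argmax.
#'
#' @param collection an [omics_collection()].
#' @param candidate_grid list of numeric vectors (one prior variance per
#'   dataset) or a matrix with one candidate per row.
#' @param reference_edges a [channel_edge_table()] of reference edges.
#' @param threshold combined-score cutoff defining positive pairs.
#' @param ... further arguments to [vdtf()] (e.g. `K`, `epochs`, `seed`).
#' @return list with `best_v_priors`, `results` (one row per candidate:
#'   priors, auprc) and `best_model`.
#' @export
tune_v_priors <- function(collection, candidate_grid, reference_edges,
                          threshold = 0.9, ...) {
  if (is.matrix(candidate_grid)) {
    candidate_grid <- lapply(seq_len(nrow(candidate_grid)),
                             function(i) candidate_grid[i, ])
  }
  stopifnot(length(candidate_grid) >= 1)
  results <- data.frame()
  best <- list(auprc = -Inf)
  for (i in seq_along(candidate_grid)) {
    vp <- candidate_grid[[i]]
    fit <- vdtf(collection, v_priors = vp, ...)
    sc <- edge_recall_auprc(as_embedding(fit), reference_edges,
                            threshold = threshold)
    results <- rbind(results, data.frame(
      candidate = i, t(stats::setNames(vp, paste0("v_prior_",
                                                  seq_along(vp)))),
      auprc = sc$auprc))
    if (sc$auprc > best$auprc) {
      best <- list(auprc = sc$auprc, v_priors = vp, model = fit)
    }
  }
  list(best_v_priors = best$v_priors, results = results,
       best_model = best$model)
}
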