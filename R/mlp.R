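# Minimal feed-forward network machinery with hand-written backpropagation
# and Adam. Gradients are fully vectorised base-R matrix algebra and are
# verified against central finite differences in the test suite.

mlp_init <- function(sizes) {
  layers <- vector("list", length(sizes) - 1L)
  for (t in seq_along(layers)) {
    fan_in <- sizes[t]
    layers[[t]] <- list(
      W = matrix(stats::rnorm(fan_in * sizes[t + 1], sd = sqrt(2 / fan_in)),
                 fan_in, sizes[t + 1]),
      b = numeric(sizes[t + 1])
    )
  }
  layers
}

# forward pass; linear = TRUE disables the activations (test/oracle mode)
mlp_forward <- function(net, X, slope = 0.01, linear = FALSE) {
  Tn <- length(net)
  inputs <- vector("list", Tn)
  preact <- vector("list", Tn)
  H <- X
  for (t in seq_len(Tn)) {
    inputs[[t]] <- H
    Z <- H %*% net[[t]]$W
    Z <- sweep(Z, 2, net[[t]]$b, `+`)
    preact[[t]] <- Z
    H <- if (t < Tn && !linear) ifelse(Z > 0, Z, slope * Z) else Z
  }
  list(out = H, inputs = inputs, preact = preact)
}

# backward pass: returns per-layer gradients and the gradient w.r.t. X
mlp_backward <- function(net, cache, dOut, slope = 0.01, linear = FALSE) {
  Tn <- length(net)
  grads <- vector("list", Tn)
  dA <- dOut
  for (t in rev(seq_len(Tn))) {
    dZ <- if (t < Tn && !linear) {
      dA * ifelse(cache$preact[[t]] > 0, 1, slope)
    } else dA
    grads[[t]] <- list(W = crossprod(cache$inputs[[t]], dZ),
                       b = colSums(dZ))
    dA <- dZ %*% t(net[[t]]$W)
  }
  list(grads = grads, dX = dA)
}

# binary cross-entropy with logits; returns loss and gradient w.r.t. logits
bce_with_logits <- function(z, y) {
  n <- length(z)
  loss <- sum(pmax(z, 0) - y * z + log1p(exp(-abs(z)))) / n
  grad <- (stats::plogis(z) - y) / n
  list(loss = loss, grad = grad)
}

# ---- Adam over nested lists of numeric arrays ------------------------------

.map_leaves <- function(f, ...) {
  args <- list(...)
  x <- args[[1]]
  if (is.list(x)) {
    out <- vector("list", length(x))
    names(out) <- names(x)
    for (i in seq_along(x)) {
      out[[i]] <- do.call(.map_leaves, c(list(f), lapply(args, `[[`, i)))
    }
    out
  } else {
    do.call(f, args)
  }
}

adam_new <- function(params) {
  list(m = .map_leaves(function(p) p * 0, params),
       v = .map_leaves(function(p) p * 0, params),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- .map_leaves(function(m, g) beta1 * m + (1 - beta1) * g,
                         state$m, grads)
  state$v <- .map_leaves(function(v, g) beta2 * v + (1 - beta2) * g^2,
                         state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  params <- .map_leaves(function(p, m, v) {
    p - lr * (m / c1) / (sqrt(v / c2) + eps)
  }, params, state$m, state$v)
  list(params = params, state = state)
}
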