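# Shared fixtures, built in code. Worlds are cached per test run so
# expensive generators run once.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

small_world <- function() cached("small_world", make_world(120, d_true = 4, seed = 3))

mid_world <- function() cached("mid_world", make_world(300, d_true = 8, seed = 5))

small_universe <- function(n = 10) {
  gene_universe(sprintf("G%03d", seq_len(n)))
}

random_embedding <- function(universe_ids, dims = 8, seed = 1) {
  m <- with_rng(seed, matrix(rnorm(length(universe_ids) * dims),
                             length(universe_ids), dims,
                             dimnames = list(universe_ids, NULL)))
  embedding_matrix(m, provenance = "random")
}

# local RNG sandbox for test-side draws
with_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# a tiny channel table built by hand
toy_channel_table <- function(prior = 0.041) {
  df <- data.frame(
    gene_a = c("G001", "G001", "G002", "G004"),
    gene_b = c("G002", "G003", "G003", "G005"),
    expa = c(0.8, 0.5, NA, 0.6),
    litc = c(0.9, NA, 0.7, NA),
    stringsAsFactors = FALSE
  )
  channel_edge_table(df, channel_names = c("expa", "litc"), prior = prior)
}

# small fitted factorization shared by the method and acceptance tests
small_fit <- function() cached("small_vdtf_fit", {
  w <- small_world()
  coll <- suppressWarnings(make_omics_collection(w, list(
    list(name = "a", n_samples = 25, noise_sd = 0.3, missing_fraction = 0.2,
         missing_bias = "by_publication"),
    list(name = "b", n_samples = 15, noise_sd = 0.3, missing_fraction = 0))))
  vdtf(coll, v_priors = c(0.05, 0.05), K = 4, hidden = 8, epochs = 8,
       batch_size = 16, global_lr = 0.02, seed = 2)
})
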