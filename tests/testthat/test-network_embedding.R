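test_that("prior removal and re-injection are exact inverses", {
  p <- 0.041
  expect_equal(remove_prior(p, p), 0)
  expect_equal(remove_prior(1, p), 1)
  expect_equal(remove_prior(1, 0.7), 1)
  expect_equal(remove_prior(0.5, p), (0.5 - 0.041) / 0.959, tolerance = 1e-12)
  # exact inverses strictly above the prior (at s = p evidence is zero and
  # the edge is dropped)
  s <- seq(p + 1e-9, 1, length.out = 50)
  expect_lt(max(abs(reinject_prior(remove_prior(s, p), p) - s)), 1e-12)
  expect_error(remove_prior(0.5, 1), "prior")
  expect_error(remove_prior(1.2, 0.1), "scores")
})

test_that("channel combination matches a step-by-step oracle", {
  p <- 0.041
  # brute-force oracle composing each step explicitly
  oracle <- function(scores, p) {
    np <- vapply(scores, function(s) max(0, (s - p) / (1 - p)), numeric(1))
    S <- 1 - prod(1 - np)
    if (S > 0) S * (1 - p) + p else 0
  }
  expect_equal(combine_channels(c(0.5, 0.5), p), oracle(c(0.5, 0.5), p),
               tolerance = 1e-12)
  # single channel round trip is the identity above the prior
  for (s in seq(p + 1e-6, 1, length.out = 9)) {
    expect_equal(combine_channels(s, p), s, tolerance = 1e-12)
  }
  expect_equal(combine_channels(p, p), 0)   # evidence at the prior: dropped
  # commutative, associative, zero channel is identity
  expect_equal(combine_channels(c(0.3, 0.8), p), combine_channels(c(0.8, 0.3), p))
  expect_equal(combine_channels(c(0.3, 0.8, 0), p),
               combine_channels(c(0.3, 0.8), p), tolerance = 1e-12)
  expect_error(combine_channels(c(0.5, 1.4), p), "scores")
})

test_that("filter_channels recomputes scores and drops empty-evidence edges", {
  tab <- toy_channel_table()
  # dropping nothing leaves combined scores unchanged
  same <- filter_channels(tab, character(0))
  expect_lt(max(abs(same$combined_score - tab$combined_score)), 1e-12)
  # dropping the literature-like channel removes literature-only edges
  expdat <- filter_channels(tab, "litc")
  litonly <- sum(is.na(tab$expa))           # edges with no other evidence
  expect_equal(nrow(expdat), nrow(tab) - litonly)
  # dropping all channels empties the table
  expect_equal(nrow(filter_channels(tab, c("expa", "litc"))), 0)
  expect_error(filter_channels(tab, "nope"), "unknown channel")
})

test_that("STRING dialect round trip preserves integer scores", {
  tab <- toy_channel_table()
  path <- withr::local_tempfile(fileext = ".txt")
  write_string_edges(tab, path)
  back <- read_string_edges(path, prior = attr(tab, "prior"))
  for (ch in c("expa", "litc")) {
    a <- tab[[ch]][!is.na(tab[[ch]])]
    b <- back[[ch]][!is.na(back[[ch]])]
    expect_equal(round(a * 1000), round(b * 1000))
  }
})

test_that("canonical edge ordering and duplicate detection", {
  df <- data.frame(gene_a = c("B", "A"), gene_b = c("A", "C"),
                   ch = c(0.8, 0.9))
  tab <- channel_edge_table(df, "ch")
  expect_true(all(tab$gene_a < tab$gene_b))
  dup <- data.frame(gene_a = c("A", "B"), gene_b = c("B", "A"),
                    ch = c(0.8, 0.9))
  expect_error(channel_edge_table(dup, "ch"), "duplicate")
})

test_that("node2vec walks have the documented geometry and biases", {
  # triangle with p = q = 1: unbiased first-order walks, uniform transitions
  tri <- channel_edge_table(data.frame(
    gene_a = c("A", "A", "B"), gene_b = c("B", "C", "C"),
    ch = c(1, 1, 1)), "ch", prior = 0)
  w <- node2vec_walks(tri, walk_length = 50, walks_per_node = 80,
                      return_p = 1, inout_q = 1, seed = 1, weighted = FALSE)
  expect_equal(nrow(w), 3 * 80)
  trans <- table(factor(w[, 2], levels = 1:3))
  # from each start the two neighbours are equally likely; pooled over
  # starts every node is visited ~uniformly at step 2
  expect_lt(max(abs(trans / sum(trans) - 1 / 3)), 0.06)

  # path A-B-C with a huge return parameter: never step back
  path <- channel_edge_table(data.frame(
    gene_a = c("A", "B"), gene_b = c("B", "C"), ch = c(1, 1)),
    "ch", prior = 0)
  wp <- node2vec_walks(path, walk_length = 4, walks_per_node = 200,
                       return_p = 1e9, inout_q = 1, seed = 2,
                       weighted = FALSE)
  starts_a <- wp[wp[, 1] == 1, ]         # A -> B -> must go C, not back to A
  expect_lt(mean(starts_a[, 3] == 1, na.rm = TRUE), 0.01)

  # isolated node: length-1 walk padded with NA
  iso <- channel_edge_table(data.frame(
    gene_a = "A", gene_b = "B", ch = 1), "ch", prior = 0)
  wi <- node2vec_walks(iso, walk_length = 5, walks_per_node = 1, seed = 1)
  expect_equal(ncol(wi), 5)
})

test_that("skip-gram embeddings separate disconnected cliques", {
  mk_clique <- function(nodes) {
    cmb <- t(combn(nodes, 2))
    data.frame(gene_a = cmb[, 1], gene_b = cmb[, 2], ch = 1)
  }
  df <- rbind(mk_clique(paste0("A", 1:6)), mk_clique(paste0("B", 1:6)))
  tab <- channel_edge_table(df, "ch", prior = 0)
  corp <- node2vec_walks(tab, walk_length = 20, walks_per_node = 20, seed = 3)
  emb <- embed_walks(corp, dims = 16, epochs = 5, seed = 3)
  V <- emb$values / sqrt(rowSums(emb$values^2))
  S <- V %*% t(V)
  ca <- grepl("^A", rownames(V))
  within <- mean(S[ca, ca][upper.tri(S[ca, ca])]) +
    mean(S[!ca, !ca][upper.tri(S[!ca, !ca])])
  between <- 2 * mean(S[ca, !ca])
  expect_gt(within, between)
  # determinism
  emb2 <- embed_walks(corp, dims = 16, epochs = 5, seed = 3)
  expect_identical(emb$values, emb2$values)
})

test_that("ppr embedding finds the hub of a star and is reproducible", {
  df <- data.frame(gene_a = "HUB", gene_b = paste0("L", 1:8), ch = 1)
  tab <- channel_edge_table(df, "ch", prior = 0)
  emb <- verse_ppr_embed(tab, dims = 16, samples_per_node = 500, seed = 4)
  V <- emb$values
  leaves <- V[rownames(V) != "HUB", ]
  hub_mean <- mean(leaves %*% V["HUB", ])
  S <- leaves %*% t(leaves)
  leaf_mean <- mean(S[upper.tri(S)])
  expect_gt(hub_mean, leaf_mean)
  expect_identical(verse_ppr_embed(tab, dims = 16, samples_per_node = 500,
                                   seed = 4)$values, emb$values)
})

test_that("ppr positive sampling degenerates to 1-hop at alpha 0", {
  df <- data.frame(gene_a = c("A", "B", "C"), gene_b = c("B", "C", "D"),
                   ch = c(1, 1, 1))
  tab <- channel_edge_table(df, "ch", prior = 0)
  pos <- ppr_positive_sample(tab, anchor = "B", alpha = 0, n = 200, seed = 1)
  expect_true(all(pos %in% c("A", "C")))   # exactly the neighbours of B
  # with damping, multi-hop positives appear
  pos2 <- ppr_positive_sample(tab, anchor = "A", alpha = 0.9, n = 500, seed = 1)
  expect_true(any(pos2 %in% c("C", "D")))
})

test_that("embedding concatenation preserves order and dimensions", {
  ids <- sprintf("G%02d", 1:6)
  e1 <- random_embedding(ids, dims = 128, seed = 1)
  e2 <- random_embedding(ids, dims = 128, seed = 2)
  cc <- concat_embeddings(e1, e2)
  expect_equal(ncol(cc$values), 256)
  # sentinel column: first block comes from e1
  sent <- e1
  sent$values[, 1] <- 99
  cs <- concat_embeddings(sent, e2)
  expect_true(all(cs$values[, 1] == 99))
  # disjoint gene sets -> error
  e3 <- random_embedding(paste0("H", 1:4), dims = 2, seed = 3)
  expect_error(concat_embeddings(e1, e3), "no gene shared")
  expect_warning(concat_embeddings(e1, random_embedding(ids[1:4], 2, 4)),
                 "dropped")
})

test_that("embeddings of a synthetic network recall its strong edges", {
  world <- mid_world()
  net <- make_channel_network(world, n_channels = 2, density = 0.05,
                              noise = 0.5, literature_channel = FALSE)
  emb <- embed_network(net, dims = 24, seed = 9,
                       walk_args = list(walks_per_node = 10),
                       verse_args = list(samples_per_node = 1000))
  r <- edge_recall_auprc(emb, net, threshold = 0.9)
  expect_gt(r$auprc, 5 * r$prevalence)
  # a random embedding sits at prevalence
  rnd <- random_embedding(rownames(emb$values), dims = 24, seed = 10)
  r0 <- edge_recall_auprc(rnd, net, threshold = 0.9)
  expect_lt(r0$auprc, 3 * r0$prevalence)
})

test_that("degenerate networks behave as documented", {
  world <- small_world()
  empty <- make_channel_network(world, density = 0)
  expect_equal(nrow(empty), 0)
  expect_error(node2vec_walks(empty), "no edges")
  expect_error(verse_ppr_embed(empty), "no edges")
})
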