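# Network embeddings: biased random walks + skip-gram, and
# personalized-PageRank noise-contrastive embedding, over a channel edge
# table. The compiled kernels live in src/graph_embed.cpp.

# compressed sparse adjacency (0-based, neighbours sorted) from an edge table
.edge_table_csr <- function(table, min_score = 0) {
  stopifnot(inherits(table, "channel_edge_table"))
  df <- as.data.frame(table)
  df <- df[df$combined_score > min_score, , drop = FALSE]
  nodes <- sort(unique(c(df$gene_a, df$gene_b)))
  idx <- stats::setNames(seq_along(nodes) - 1L, nodes)
  from <- c(idx[df$gene_a], idx[df$gene_b])
  to <- c(idx[df$gene_b], idx[df$gene_a])
  w <- rep(df$combined_score, 2)
  ord <- order(from, to)
  from <- from[ord]; to <- to[ord]; w <- w[ord]
  offsets <- c(0L, cumsum(tabulate(from + 1L, nbins = length(nodes))))
  list(nodes = nodes, offsets = as.integer(offsets),
       adj = as.integer(to), wts = as.numeric(w))
}

#' Generate a biased random-walk corpus (node2vec style)
#'
#' Second-order biased walks over the network: from the current node, the
#' unnormalized probability of stepping to a neighbour is its edge weight
#' multiplied by `1/return_p` for the previous node, 1 for common neighbours
#' of the previous and current node, and `1/inout_q` otherwise. Isolated
#' nodes yield length-1 walks. Defaults follow common practice for
#' protein-interaction networks: walk length 80, 10 walks per source,
#' return parameter 0.3, in-out parameter 1.
#'
#' @param table a [channel_edge_table()]; combined scores are the edge
#'   weights.
#' @param walk_length,walks_per_node walk geometry.
#' @param return_p,inout_q the second-order bias parameters.
#' @param seed RNG seed.
#' @param weighted multiply biases by edge weights? Default TRUE.
#' @return object of class `walk_corpus`: integer matrix of 1-based node
#'   indices (NA-padded rows), with attribute `nodes` giving gene ids.
#' @export
node2vec_walks <- function(table, walk_length = 80, walks_per_node = 10,
                           return_p = 0.3, inout_q = 1, seed = 1,
                           weighted = TRUE) {
  csr <- .edge_table_csr(table)
  if (length(csr$nodes) == 0L) stop("network has no edges")
  walks <- cpp_node2vec_walks(csr$offsets, csr$adj, csr$wts,
                              as.integer(walk_length),
                              as.integer(walks_per_node),
                              return_p, inout_q, as.integer(seed), weighted)
  structure(walks, nodes = csr$nodes, class = c("walk_corpus", class(walks)))
}

#' Embed a walk corpus by skip-gram with negative sampling
#'
#' Word2vec-style training over the walk corpus: each (center, context) pair
#' within the window is a positive example, with `negatives` nodes drawn
#' from the unigram^0.75 distribution as negatives; one SGD epoch by
#' default.
#'
#' @param corpus a [node2vec_walks()] corpus.
#' @param dims embedding dimensionality (default 128).
#' @param epochs SGD epochs (default 1).
#' @param window context window (default 10).
#' @param negatives negative samples per positive (default 5).
#' @param lr initial learning rate (linearly decayed).
#' @param seed RNG seed.
#' @return an [embedding_matrix()] over the corpus' nodes.
#' @export
embed_walks <- function(corpus, dims = 128, epochs = 1, window = 10,
                        negatives = 5, lr = 0.025, seed = 1) {
  stopifnot(inherits(corpus, "walk_corpus"))
  nodes <- attr(corpus, "nodes")
  if (nrow(corpus) == 0L || length(nodes) == 0L) stop("empty walk corpus")
  emb <- cpp_sgns(unclass(corpus), length(nodes), as.integer(dims),
                  as.integer(window), as.integer(negatives),
                  as.integer(epochs), lr, as.integer(seed))
  rownames(emb) <- nodes
  embedding_matrix(emb, provenance = "node2vec")
}

#' Personalized-PageRank noise-contrastive embedding (VERSE style)
#'
#' Learns node vectors whose similarities match personalized PageRank: for
#' each anchor, positives are drawn by a damped random walk (one step, then
#' continue with probability `alpha`), negatives uniformly; vectors are
#' updated by logistic noise-contrastive gradients.
#'
#' @param table a [channel_edge_table()].
#' @param dims embedding dimensionality (default 128).
#' @param alpha PPR damping: continuation probability of the walk (default
#'   0.85). `alpha = 0` stops after one step, so positives are exactly
#'   1-hop neighbours.
#' @param negatives negative samples per positive (default 3).
#' @param samples_per_node positive samples per node per epoch.
#' @param epochs passes over the node set.
#' @param lr initial learning rate.
#' @param seed RNG seed.
#' @param weighted use combined scores as step weights? Default TRUE.
#' @return an [embedding_matrix()].
#' @export
verse_ppr_embed <- function(table, dims = 128, alpha = 0.85, negatives = 3,
                            samples_per_node = 2000, epochs = 1, lr = 0.025,
                            seed = 1, weighted = TRUE) {
  csr <- .edge_table_csr(table)
  if (length(csr$nodes) == 0L) stop("network has no edges")
  emb <- cpp_ppr_nce(csr$offsets, csr$adj, csr$wts, length(csr$nodes),
                     as.integer(dims), alpha, as.integer(negatives),
                     as.integer(samples_per_node), as.integer(epochs),
                     lr, as.integer(seed), weighted)
  rownames(emb) <- csr$nodes
  embedding_matrix(emb, provenance = "verse_ppr")
}

#' Sample personalized-PageRank positives from an anchor
#'
#' Diagnostic utility exposing the positive-sampling convention of
#' [verse_ppr_embed()]: from the anchor, take one step, then keep walking
#' with probability `alpha`; the stopping node is the positive. At
#' `alpha = 0` positives are exactly the anchor's 1-hop neighbours.
#'
#' @param table a [channel_edge_table()].
#' @param anchor gene id to sample from.
#' @param alpha PPR damping (continuation probability).
#' @param n number of samples.
#' @param seed RNG seed.
#' @param weighted weight steps by combined score?
#' @return character vector of sampled positive gene ids.
#' @export
ppr_positive_sample <- function(table, anchor, alpha = 0.85, n = 100,
                                seed = 1, weighted = TRUE) {
  csr <- .edge_table_csr(table)
  a0 <- match(anchor, csr$nodes)
  if (is.na(a0)) stop("anchor not in network: ", anchor)
  step <- function(cur) {
    lo <- csr$offsets[cur] + 1L
    hi <- csr$offsets[cur + 1L]
    if (hi < lo) return(NA_integer_)
    nb <- csr$adj[lo:hi] + 1L
    w <- if (weighted) csr$wts[lo:hi] else rep(1, length(nb))
    nb[sample.int(length(nb), 1, prob = w)]
  }
  with_seed(seed, {
    vapply(seq_len(n), function(i) {
      v <- step(a0)
      if (is.na(v)) return(NA_character_)
      while (stats::runif(1) < alpha) {
        nxt <- step(v)
        if (is.na(nxt)) break
        v <- nxt
      }
      csr$nodes[v]
    }, character(1))
  })
}

#' Concatenate two embeddings column-wise
#'
#' Rows are matched on the intersection of gene indices; genes missing from
#' either side are dropped with a warning. Columns of `e1` come first.
#'
#' @param e1,e2 [embedding_matrix()] objects.
#' @return an [embedding_matrix()] with `ncol(e1) + ncol(e2)` dimensions.
#' @export
concat_embeddings <- function(e1, e2) {
  stopifnot(inherits(e1, "embedding_matrix"), inherits(e2, "embedding_matrix"))
  common <- intersect(rownames(e1$values), rownames(e2$values))
  if (length(common) == 0L) stop("no gene shared between the two embeddings")
  dropped <- (nrow(e1$values) - length(common)) + (nrow(e2$values) - length(common))
  if (dropped > 0) warning(dropped, " gene row(s) dropped in concatenation")
  v <- cbind(e1$values[common, , drop = FALSE], e2$values[common, , drop = FALSE])
  colnames(v) <- paste0("d", seq_len(ncol(v)))
  embedding_matrix(v, provenance = paste(e1$provenance, e2$provenance, sep = "+"))
}

#' Embed a network with node2vec and PPR embeddings concatenated
#'
#' Convenience wrapper reproducing the standard recipe: a skip-gram
#' embedding of biased walks and a PPR noise-contrastive embedding, each of
#' `dims` dimensions, concatenated to `2 * dims`.
#'
#' @param table a [channel_edge_table()].
#' @param dims per-algorithm dimensionality (default 128).
#' @param seed RNG seed.
#' @param walk_args,sgns_args,verse_args argument lists forwarded to
#'   [node2vec_walks()], [embed_walks()] and [verse_ppr_embed()].
#' @return an [embedding_matrix()] with `2 * dims` columns.
#' @export
embed_network <- function(table, dims = 128, seed = 1, walk_args = list(),
                          sgns_args = list(), verse_args = list()) {
  corpus <- do.call(node2vec_walks,
                    c(list(table = table, seed = seed), walk_args))
  e1 <- do.call(embed_walks,
                c(list(corpus = corpus, dims = dims, seed = seed + 1L),
                  sgns_args))
  e2 <- do.call(verse_ppr_embed,
                c(list(table = table, dims = dims, seed = seed + 2L),
                  verse_args))
  concat_embeddings(e1, e2)
}

#' Per-gene neighbourhood fidelity of an embedding
#'
#' For every gene, the average precision of recovering its `k` nearest
#' reference neighbours when the other genes are ranked by embedding
#' distance. The reference is a coordinate matrix whose Euclidean
#' geometry defines the true neighbourhoods (in synthetic worlds, the
#' latent gene-function coordinates). This is the per-gene diagnostic of
#' where an embedding is locally reliable; stratifying it by publication
#' count exposes annotation-inequality effects that coarse aggregate
#' metrics wash out.
#'
#' @param embedding an [embedding_matrix()].
#' @param reference matrix of reference coordinates with gene-id rownames
#'   (only genes shared with the embedding are scored).
#' @param k neighbourhood size (default 10).
#' @return named numeric vector: per-gene average precision.
#' @export
neighborhood_fidelity <- function(embedding, reference, k = 10) {
  stopifnot(inherits(embedding, "embedding_matrix"),
            !is.null(rownames(reference)))
  g <- intersect(rownames(embedding$values), rownames(reference))
  if (length(g) < k + 2) stop("too few shared genes")
  V <- embedding$values[g, , drop = FALSE]
  Dref <- as.matrix(stats::dist(reference[g, , drop = FALSE]))
  ap <- vapply(seq_along(g), function(i) {
    truth <- rank(Dref[i, ]) <= k + 1 & seq_along(g) != i
    d2 <- colSums((t(V) - V[i, ])^2)
    average_precision(-d2[-i], truth[-i])
  }, numeric(1))
  stats::setNames(ap, g)
}

#' Edge-recall quality of an embedding
#'
#' The hyperparameter objective used for the factorization's prior
#' variances: rank gene pairs by ascending embedding Euclidean distance and
#' compute the average precision of recovering high-confidence network
#' edges (combined score above `threshold`). For large universes the pair
#' set is a seeded subsample that always contains all positive pairs.
#'
#' @param embedding an [embedding_matrix()].
#' @param table a [channel_edge_table()] providing reference edges.
#' @param threshold combined-score cutoff defining positives (default 0.9).
#' @param max_pairs cap on the number of scored pairs (default 2e6).
#' @param seed subsampling seed.
#' @return list with `auprc` and `prevalence`.
#' @export
edge_recall_auprc <- function(embedding, table, threshold = 0.9,
                              max_pairs = 2e6, seed = 1) {
  stopifnot(inherits(embedding, "embedding_matrix"),
            inherits(table, "channel_edge_table"))
  genes <- rownames(embedding$values)
  n <- length(genes)
  idx <- stats::setNames(seq_len(n), genes)
  df <- as.data.frame(table)
  df <- df[df$combined_score > threshold &
             df$gene_a %in% genes & df$gene_b %in% genes, , drop = FALSE]
  if (nrow(df) == 0L) stop("no reference edge above threshold among embedded genes")
  pos_key <- (pmin(idx[df$gene_a], idx[df$gene_b]) - 1) * n +
    pmax(idx[df$gene_a], idx[df$gene_b])
  n_pairs <- n * (n - 1) / 2
  if (n_pairs > max_pairs) {
    pairs <- with_seed(seed, {
      i <- sample.int(n, max_pairs, replace = TRUE)
      j <- sample.int(n, max_pairs, replace = TRUE)
      keep <- i < j
      cbind(i[keep], j[keep])
    })
    key <- (pairs[, 1] - 1) * n + pairs[, 2]
    new <- !(key %in% pos_key) & !duplicated(key)
    pairs <- pairs[new, , drop = FALSE]
    pi_ <- cbind(c(pmin(idx[df$gene_a], idx[df$gene_b]), pairs[, 1]),
                 c(pmax(idx[df$gene_a], idx[df$gene_b]), pairs[, 2]))
    labels <- c(rep(1L, nrow(df)), rep(0L, nrow(pairs)))
  } else {
    iu <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    pi_ <- iu
    key <- (iu[, 1] - 1) * n + iu[, 2]
    labels <- as.integer(key %in% pos_key)
  }
  V <- embedding$values
  d2 <- rowSums((V[pi_[, 1], , drop = FALSE] - V[pi_[, 2], , drop = FALSE])^2)
  list(auprc = average_precision(-d2, labels, ties = "grouped"),
       prevalence = mean(labels))
}
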