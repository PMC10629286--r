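#' Channel-scored edge table
#'
#' An undirected weighted network in the STRING style: one row per gene
#' pair, one score column per evidence channel (values in \[0,1\]) and a
#' combined score obtained by removing the shared evidence prior from each
#' channel, combining with `S = 1 - prod(1 - S_c)` and re-injecting the
#' prior. Pairs are stored in canonical order (`gene_a < gene_b`) with no
#' duplicates.
#'
#' @param df data.frame with columns `gene_a`, `gene_b` and one numeric
#'   column per channel.
#' @param channel_names character vector naming the channel columns (created
#'   as empty columns if `df` has no rows).
#' @param prior scalar evidence prior in \[0, 1).
#' @return object of class `channel_edge_table`: the data.frame with an
#'   added `combined_score` column and attributes `channel_names`, `prior`.
#' @export
channel_edge_table <- function(df, channel_names, prior = 0.041) {
  if (prior < 0 || prior >= 1) stop("prior must be in [0, 1)")
  stopifnot(is.data.frame(df), all(c("gene_a", "gene_b") %in% names(df)))
  for (ch in channel_names) if (!ch %in% names(df)) df[[ch]] <- numeric(0)
  if (nrow(df) > 0) {
    swap <- df$gene_a > df$gene_b
    if (any(swap)) {
      tmp <- df$gene_a[swap]
      df$gene_a[swap] <- df$gene_b[swap]
      df$gene_b[swap] <- tmp
    }
    key <- paste(df$gene_a, df$gene_b, sep = "\r")
    if (anyDuplicated(key)) stop("duplicate edges in channel table")
    sc <- as.matrix(df[, channel_names, drop = FALSE])
    if (any(sc < 0 | sc > 1, na.rm = TRUE)) stop("channel scores must be in [0, 1]")
    df$combined_score <- combine_channels(sc, prior)
    df <- df[df$combined_score > 0, , drop = FALSE]
    rownames(df) <- NULL
  } else {
    df$combined_score <- numeric(0)
  }
  structure(df, channel_names = channel_names, prior = prior,
            class = c("channel_edge_table", "data.frame"))
}

#' @exportS3Method
print.channel_edge_table <- function(x, ...) {
  cat("<channel_edge_table> ", nrow(x), " edges, channels: ",
      paste(attr(x, "channel_names"), collapse = ", "),
      " (prior ", attr(x, "prior"), ")\n", sep = "")
  invisible(x)
}

#' Remove the evidence prior from a channel score
#'
#' The STRING-documented prior correction: `(score - p) / (1 - p)`, clamped
#' at 0. Exact inverse of [reinject_prior()] on `[p, 1]`.
#'
#' @param score numeric scores in \[0, 1\].
#' @param p evidence prior, in \[0, 1).
#' @return prior-free scores in \[0, 1\].
#' @export
remove_prior <- function(score, p) {
  if (p < 0 || p >= 1) stop("prior must be in [0, 1)")
  if (any(score < 0 | score > 1)) stop("scores must be in [0, 1]")
  pmax(0, (score - p) / (1 - p))
}

#' Re-inject the evidence prior into a prior-free score
#'
#' `s * (1 - p) + p` for positive evidence; a score of exactly 0 (no
#' remaining evidence) stays 0, so edges whose only evidence was removed
#' drop out of the network.
#'
#' @param score prior-free scores in \[0, 1\].
#' @param p evidence prior.
#' @return scores with the prior re-injected.
#' @export
reinject_prior <- function(score, p) {
  if (p < 0 || p >= 1) stop("prior must be in [0, 1)")
  ifelse(score > 0, score * (1 - p) + p, 0)
}

#' Combine evidence channels into one score
#'
#' Removes the prior from every channel, combines with the noisy-or formula
#' `S = 1 - prod_c(1 - S_c)`, and re-injects the prior. `NA` channel entries
#' are treated as absent evidence.
#'
#' @param scores numeric matrix (edges x channels) or vector (one edge) of
#'   raw channel scores in \[0, 1\].
#' @param p evidence prior.
#' @return combined scores, one per edge.
#' @export
combine_channels <- function(scores, p) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  if (any(scores < 0 | scores > 1, na.rm = TRUE)) stop("scores must be in [0, 1]")
  if (ncol(scores) == 0L) return(rep(0, nrow(scores)))
  np <- matrix(remove_prior(ifelse(is.na(scores), 0, scores), p),
               nrow = nrow(scores))
  S <- 1 - apply(1 - np, 1, prod)
  reinject_prior(S, p)
}

#' Drop evidence channels and recompute combined scores
#'
#' Removes the named channels (e.g. text mining and curated databases,
#' including any cross-species "transferred" variants, which are simply more
#' channel names) and recomputes the combined score from the remaining
#' channels. Edges with no remaining evidence are removed entirely.
#'
#' @param table a [channel_edge_table()].
#' @param drop character vector of channel names to remove.
#' @return a [channel_edge_table()] with the remaining channels.
#' @export
filter_channels <- function(table, drop) {
  stopifnot(inherits(table, "channel_edge_table"))
  channels <- attr(table, "channel_names")
  unknown <- setdiff(drop, channels)
  if (length(unknown)) stop("unknown channel(s): ", paste(unknown, collapse = ", "))
  keep <- setdiff(channels, drop)
  df <- as.data.frame(table)
  df <- df[, setdiff(names(df), c(drop, "combined_score")), drop = FALSE]
  channel_edge_table(df, channel_names = keep, prior = attr(table, "prior"))
}

#' Read / write a STRING-dialect edge file
#'
#' Space- or tab-separated file with a header, two node columns and integer
#' channel scores 0-1000 (the writer multiplies by 1000 and rounds; the
#' reader divides), for bit-compatibility with the real resource. All
#' columns other than the first two and any `combined_score` column are
#' taken as channels.
#'
#' @param path file path.
#' @param prior evidence prior used to recompute combined scores.
#' @return a [channel_edge_table()].
#' @export
read_string_edges <- function(path, prior = 0.041) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("STRING edge file needs >= 3 columns: ", path)
  names(df)[1:2] <- c("gene_a", "gene_b")
  channels <- setdiff(names(df), c("gene_a", "gene_b", "combined_score"))
  df$combined_score <- NULL
  for (ch in channels) df[[ch]] <- df[[ch]] / 1000
  channel_edge_table(df, channel_names = channels, prior = prior)
}

#' @rdname read_string_edges
#' @param table a [channel_edge_table()].
#' @export
write_string_edges <- function(table, path) {
  stopifnot(inherits(table, "channel_edge_table"))
  channels <- attr(table, "channel_names")
  df <- as.data.frame(table)[, c("gene_a", "gene_b", channels, "combined_score")]
  for (ch in c(channels, "combined_score")) df[[ch]] <- as.integer(round(df[[ch]] * 1000))
  utils::write.table(df, path, sep = " ", quote = FALSE, row.names = FALSE)
  invisible(path)
}
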