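#' Read a genes-by-samples TSV matrix
#'
#' Expects a tab-separated file with a header row of sample ids and the first
#' column holding gene ids. Genes absent from the universe are dropped with a
#' warning naming the count; duplicate gene rows and empty files are errors.
#'
#' @param path file path.
#' @param universe a [gene_universe()].
#' @return an [expression_matrix()].
#' @export
read_matrix_tsv <- function(path, universe) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) stop("empty or malformed matrix file: ", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate gene row in ", path, ": ",
                               ids[duplicated(ids)][1])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  expression_matrix(m, universe)
}

#' Write a genes-by-samples TSV matrix
#'
#' Inverse of [read_matrix_tsv()]; values are written with full precision
#' (`format = "%.17g"`-equivalent via `as.character`) so a round trip
#' reproduces them bitwise.
#'
#' @param m an [expression_matrix()].
#' @param path output path.
#' @export
write_matrix_tsv <- function(m, path) {
  stopifnot(inherits(m, "expression_matrix"))
  df <- data.frame(gene_id = rownames(m$values),
                   # full decimal expansion keeps the round trip bitwise
                   vapply(seq_len(ncol(m$values)), function(j)
                     sprintf("%.17g", m$values[, j]), character(nrow(m$values))),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", m$sample_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene list file
#'
#' One gene id per line; `#` starts a comment line. Unknown ids are dropped
#' with a warning; a file whose ids are all unknown is an error.
#'
#' @param path file path.
#' @param universe a [gene_universe()].
#' @param name list name (defaults to file name without extension).
#' @return a [gene_list()].
#' @export
read_gene_list <- function(path, universe, name = NULL) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty gene list file: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  gene_list(lines, universe, name = name, source_tag = path)
}

#' Write a gene list file
#' @param gl a [gene_list()].
#' @param path output path.
#' @export
write_gene_list <- function(gl, path) {
  stopifnot(inherits(gl, "gene_list"))
  writeLines(gl$genes, path)
  invisible(path)
}

#' Read a two-column id mapping table
#'
#' TSV with columns `from` and `to` (header optional when `header = FALSE`).
#' Applied to external ids before universe intersection; no remote lookups.
#'
#' @param path file path.
#' @param header does the file have a header row?
#' @return named character vector mapping from -> to.
#' @export
read_id_mapping <- function(path, header = TRUE) {
  df <- utils::read.delim(path, header = header, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("mapping table needs two columns: ", path)
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Write / read an embedding matrix
#'
#' Two on-disk forms: a TSV (`gene_id` column + one column per dimension,
#' printed at 8 decimals; round trip accurate to 5e-9) and a binary container
#' (RDS serialisation of the matrix with its gene index; round trip bitwise).
#' The format is chosen from the file extension: `.rds` is binary, anything
#' else is TSV.
#'
#' @param emb an [embedding_matrix()].
#' @param path output path (`.tsv` or `.rds`).
#' @export
write_embedding <- function(emb, path) {
  stopifnot(inherits(emb, "embedding_matrix"))
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    saveRDS(emb, path)
  } else {
    df <- data.frame(gene_id = rownames(emb$values),
                     vapply(seq_len(ncol(emb$values)), function(j)
                       sprintf("%.8f", emb$values[, j]),
                       character(nrow(emb$values))),
                     check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df) <- c("gene_id", paste0("d", seq_len(ncol(emb$values))))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_embedding
#' @param path file path to read.
#' @return an [embedding_matrix()].
#' @export
read_embedding <- function(path) {
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    emb <- readRDS(path)
    stopifnot(inherits(emb, "embedding_matrix"))
    return(emb)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty embedding file: ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  embedding_matrix(m, provenance = basename(path))
}
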