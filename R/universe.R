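#' Gene universe
#'
#' The ordered set of gene identifiers every downstream matrix, list and
#' network refers into. Identifier matching is case-sensitive and exact;
#' nothing in the package silently coerces gene ids.
#'
#' @param gene_ids character vector of unique identifiers (Ensembl-style).
#' @return object of class `gene_universe` with elements `gene_ids` and
#'   `index` (named integer map id -> position).
#' @export
gene_universe <- function(gene_ids) {
  gene_ids <- as.character(gene_ids)
  if (anyNA(gene_ids) || any(gene_ids == "")) stop("empty or NA gene ids")
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids in universe: ", gene_ids[duplicated(gene_ids)][1])
  }
  structure(
    list(gene_ids = gene_ids,
         index = stats::setNames(seq_along(gene_ids), gene_ids)),
    class = "gene_universe"
  )
}

#' @exportS3Method
print.gene_universe <- function(x, ...) {
  cat("<gene_universe> ", length(x$gene_ids), " genes (",
      x$gene_ids[1], " ... ", x$gene_ids[length(x$gene_ids)], ")\n", sep = "")
  invisible(x)
}

#' @export
length.gene_universe <- function(x) length(x$gene_ids)

#' Expression matrix bound to a gene universe
#'
#' Container for a genes-by-samples numeric matrix together with the boolean
#' mask of universe genes present in this dataset. Row count always equals
#' the number of masked-in genes, and rownames are the masked-in gene ids in
#' universe order.
#'
#' @param values numeric matrix, rownames = gene ids.
#' @param universe a [gene_universe()].
#' @param sample_ids optional column ids (default from colnames).
#' @return object of class `expression_matrix` with `values`, `gene_mask`,
#'   `sample_ids`, `gene_ids`.
#' @export
expression_matrix <- function(values, universe, sample_ids = colnames(values)) {
  stopifnot(inherits(universe, "gene_universe"), is.matrix(values))
  ids <- rownames(values)
  if (is.null(ids)) stop("values must have gene ids as rownames")
  if (anyDuplicated(ids)) stop("duplicate gene rows: ", ids[duplicated(ids)][1])
  known <- ids %in% universe$gene_ids
  if (!all(known)) {
    warning(sum(!known), " gene(s) not in universe dropped (e.g. ",
            ids[!known][1], ")")
    values <- values[known, , drop = FALSE]
    ids <- ids[known]
  }
  if (nrow(values) == 0L) stop("no genes left after universe intersection")
  ord <- order(universe$index[ids])
  values <- values[ord, , drop = FALSE]
  mask <- universe$gene_ids %in% rownames(values)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(values)))
  structure(
    list(values = values, gene_mask = mask, sample_ids = sample_ids,
         gene_ids = rownames(values)),
    class = "expression_matrix"
  )
}

#' @exportS3Method
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples (", sum(x$gene_mask), "/", length(x$gene_mask),
      " universe genes present)\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Gene list
#'
#' A named set of genes from the universe (e.g. a curated disease-gene list
#' or a trait-associated set). Unknown ids are dropped with a warning; a list
#' with no known gene is an error.
#'
#' @param genes character vector of gene ids.
#' @param universe a [gene_universe()].
#' @param name list name.
#' @param source_tag free-text provenance tag.
#' @return object of class `gene_list` with `name`, `genes`, `source_tag`.
#' @export
gene_list <- function(genes, universe, name = "genelist", source_tag = "") {
  genes <- unique(as.character(genes))
  known <- genes %in% universe$gene_ids
  if (!any(known)) stop("gene list '", name, "': no gene found in universe")
  if (!all(known)) {
    warning("gene list '", name, "': dropped ", sum(!known),
            " unknown id(s) (e.g. ", genes[!known][1], ")")
  }
  structure(list(name = name, genes = genes[known], source_tag = source_tag),
            class = "gene_list")
}

#' @exportS3Method
print.gene_list <- function(x, ...) {
  cat("<gene_list> '", x$name, "': ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Embedding matrix
#'
#' A genes-by-dimensions numeric matrix with gene ids as rownames and a
#' provenance tag; the common currency of the package (omics, network and
#' concatenated embeddings, as well as external feature matrices).
#'
#' @param values numeric matrix with gene-id rownames.
#' @param provenance free-text tag (e.g. "omics", "string_full").
#' @return object of class `embedding_matrix`.
#' @export
embedding_matrix <- function(values, provenance = "") {
  stopifnot(is.matrix(values), !is.null(rownames(values)))
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids in embedding")
  if (!all(is.finite(values))) stop("non-finite values in embedding")
  structure(list(values = values, provenance = provenance),
            class = "embedding_matrix")
}

#' @exportS3Method
print.embedding_matrix <- function(x, ...) {
  cat("<embedding_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " dims", if (nzchar(x$provenance)) paste0(" [", x$provenance, "]"),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.embedding_matrix <- function(x) dim(x$values)
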