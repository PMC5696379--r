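#' Gene-by-sample count matrix with annotation
#'
#' The basic container moved between pipeline stages: a dense matrix of
#' non-negative integer read counts with gene identifiers, display symbols,
#' optional gene lengths (needed for RPKM), and per-sample metadata such as
#' the developmental stage or sorted population each library came from.
#'
#' @param counts numeric matrix, genes in rows, samples in columns. All
#'   entries must be non-negative and integral (stored as double).
#' @param gene_ids character vector of unique gene identifiers (row names).
#' @param gene_symbols character vector of display symbols; defaults to
#'   `gene_ids`. Empty symbols are allowed and mark unannotated genes.
#' @param gene_lengths optional positive numeric vector of gene (transcript)
#'   lengths in base pairs; required downstream for RPKM transforms.
#' @param sample_ids character vector of unique sample/cell identifiers.
#' @param sample_meta optional data.frame keyed by sample id (rows in the
#'   same order as `sample_ids`), typically with a `group` column.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts,
                         gene_ids = rownames(counts),
                         gene_symbols = NULL,
                         gene_lengths = NULL,
                         sample_ids = colnames(counts),
                         sample_meta = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(gene_ids)) stop("gene_ids are required (set rownames or pass gene_ids)")
  if (is.null(sample_ids)) stop("sample_ids are required (set colnames or pass sample_ids)")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(counts) != length(gene_ids))
    stop("counts has ", nrow(counts), " rows but ", length(gene_ids), " gene_ids")
  if (ncol(counts) != length(sample_ids))
    stop("counts has ", ncol(counts), " columns but ", length(sample_ids), " sample_ids")
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids")
  if (anyDuplicated(sample_ids)) stop("duplicate sample_ids")
  if (length(counts) && (min(counts) < 0)) stop("negative counts")
  if (length(counts) && any(counts != round(counts))) stop("non-integer counts")
  if (is.null(gene_symbols)) gene_symbols <- gene_ids
  gene_symbols <- as.character(gene_symbols)
  if (length(gene_symbols) != length(gene_ids))
    stop("gene_symbols length does not match gene_ids")
  if (!is.null(gene_lengths)) {
    gene_lengths <- as.numeric(gene_lengths)
    if (length(gene_lengths) != length(gene_ids))
      stop("gene_lengths length does not match gene_ids")
    if (any(!is.finite(gene_lengths)) || any(gene_lengths <= 0))
      stop("gene_lengths must be positive")
  }
  if (!is.null(sample_meta)) {
    sample_meta <- as.data.frame(sample_meta)
    if (nrow(sample_meta) != length(sample_ids))
      stop("sample_meta rows do not match sample_ids")
    rownames(sample_meta) <- sample_ids
  }
  dimnames(counts) <- list(gene_ids, sample_ids)
  structure(
    list(counts = counts, gene_ids = gene_ids, gene_symbols = gene_symbols,
         gene_lengths = gene_lengths, sample_ids = sample_ids,
         sample_meta = sample_meta),
    class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
#' @method print count_matrix
print.count_matrix <- function(x, ...) {
  cat("count_matrix: ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples\n", sep = "")
  if (!is.null(x$gene_lengths)) cat("  gene lengths: present\n")
  if (!is.null(x$sample_meta))
    cat("  sample_meta columns: ",
        paste(colnames(x$sample_meta), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Subset a count_matrix by gene and/or sample index
#'
#' Keeps all annotation slots aligned. Indices may be logical, integer or
#' character (matched against ids).
#'
#' @param x a `count_matrix`
#' @param i gene index
#' @param j sample index
#' @param ... ignored
#' @export
`[.count_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$gene_ids)
  if (missing(j)) j <- seq_along(x$sample_ids)
  if (is.character(i)) i <- match(i, x$gene_ids)
  if (is.character(j)) j <- match(j, x$sample_ids)
  count_matrix(
    x$counts[i, j, drop = FALSE],
    gene_ids = x$gene_ids[i],
    gene_symbols = x$gene_symbols[i],
    gene_lengths = if (!is.null(x$gene_lengths)) x$gene_lengths[i],
    sample_ids = x$sample_ids[j],
    sample_meta = if (!is.null(x$sample_meta)) x$sample_meta[j, , drop = FALSE])
}

#' Per-sample group labels from a count_matrix
#'
#' @param x a `count_matrix` with a `group` column in `sample_meta`
#' @return character vector of labels, one per sample
#' @export
sample_groups <- function(x) {
  if (is.null(x$sample_meta) || is.null(x$sample_meta$group))
    stop("count_matrix has no sample_meta$group labels")
  as.character(x$sample_meta$group)
}

#' Real-valued expression matrix with normalization provenance
#'
#' @param values numeric matrix, genes x samples
#' @param normalization one of `cpm`, `log2cpm`, `log2rpkm`,
#'   `quantile_log2cpm`, `standardized`
#' @param prior_count prior count used in a log transform, if any
#' @param constant_genes optional logical vector flagging rows that were
#'   constant at standardization time
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values,
                        normalization = c("cpm", "log2cpm", "log2rpkm",
                                          "quantile_log2cpm", "standardized"),
                        prior_count = NA_real_,
                        constant_genes = NULL) {
  normalization <- match.arg(normalization)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expr_matrix values need gene and sample dimnames")
  structure(
    list(values = values, normalization = normalization,
         prior_count = prior_count, constant_genes = constant_genes),
    class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
#' @method print expr_matrix
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix (", x$normalization, "): ", nrow(x$values), " genes x ",
      ncol(x$values), " samples\n", sep = "")
  invisible(x)
}

#' Named lineage signature gene sets
#'
#' Disjoint, named gene lists (e.g. basal / LP / ML) together with the
#' per-gene log2 fold changes and FDRs recorded at derivation time.
#'
#' @param sets named list of character vectors of gene ids
#' @param stats optional data.frame with columns `gene_id`, `class`,
#'   `log2fc`, `fdr`
#' @param provenance free-text note on where the sets came from
#' @export
signature_set <- function(sets, stats = NULL, provenance = "") {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("signature sets must be named")
  if (anyDuplicated(names(sets))) stop("duplicate signature set names")
  sets <- lapply(sets, as.character)
  for (nm in names(sets))
    if (anyDuplicated(sets[[nm]])) stop("duplicate gene ids in set ", nm)
  all_ids <- unlist(sets, use.names = FALSE)
  if (anyDuplicated(all_ids))
    stop("signature sets must be disjoint")
  structure(list(sets = sets, stats = stats, provenance = provenance),
            class = "signature_set")
}

#' @export
#' @method print signature_set
print.signature_set <- function(x, ...) {
  cat("signature_set with", length(x$sets), "classes:\n")
  for (nm in names(x$sets))
    cat("  ", nm, ": ", length(x$sets[[nm]]), " genes\n", sep = "")
  invisible(x)
}

#' Ordered collection of gene sets (GMT-style)
#'
#' @param sets named list of character vectors
#' @param provenance free text
#' @export
gene_set_collection <- function(sets, provenance = "") {
  if (length(sets) && (is.null(names(sets)) || any(names(sets) == "")))
    stop("gene sets must be named")
  if (anyDuplicated(names(sets))) stop("duplicate gene set names")
  for (nm in names(sets))
    if (anyDuplicated(sets[[nm]])) stop("duplicate ids within set ", nm)
  structure(list(sets = lapply(sets, as.character), provenance = provenance),
            class = "gene_set_collection")
}

#' @export
#' @method print gene_set_collection
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x$sets), "sets\n")
  invisible(x)
}
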