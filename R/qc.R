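#' QC thresholds for cell and gene filtering
#'
#' Defaults follow the deep single-cell protocol: drop cells with fewer
#' than 100,000 assigned read pairs or fewer than 1500 detected genes
#' (relaxed to 50,000 and 1000 for the relaxed threshold pair), and drop
#' genes that fail to achieve 1 CPM in at least 3 cells.
#'
#' @param min_read_pairs strict minimum assigned total per cell
#' @param min_detected_genes strict minimum detected genes per cell
#' @param relaxed_min_read_pairs relaxed minimum assigned total
#' @param relaxed_min_detected_genes relaxed minimum detected genes
#' @param min_cpm CPM a gene must achieve
#' @param min_cells_at_cpm in at least this many cells
#' @export
qc_thresholds <- function(min_read_pairs = 100000,
                          min_detected_genes = 1500,
                          relaxed_min_read_pairs = 50000,
                          relaxed_min_detected_genes = 1000,
                          min_cpm = 1,
                          min_cells_at_cpm = 3) {
  th <- list(min_read_pairs = min_read_pairs,
             min_detected_genes = min_detected_genes,
             relaxed_min_read_pairs = relaxed_min_read_pairs,
             relaxed_min_detected_genes = relaxed_min_detected_genes,
             min_cpm = min_cpm, min_cells_at_cpm = min_cells_at_cpm)
  if (any(unlist(th) <= 0)) stop("QC thresholds must be positive")
  if (relaxed_min_read_pairs > min_read_pairs ||
      relaxed_min_detected_genes > min_detected_genes)
    stop("relaxed thresholds must not exceed strict thresholds")
  structure(th, class = "qc_thresholds")
}

qc_report <- function(removed_cells = character(0),
                      cell_reasons = character(0),
                      removed_genes = character(0),
                      gene_reasons = character(0),
                      kept_dims) {
  structure(list(
    removed_cells = data.frame(sample_id = removed_cells,
                               reason = cell_reasons),
    removed_genes = data.frame(gene_id = removed_genes,
                               reason = gene_reasons),
    kept_dims = kept_dims), class = "qc_report")
}

#' @export
#' @method print qc_report
print.qc_report <- function(x, ...) {
  cat("qc_report: removed", nrow(x$removed_genes), "genes,",
      nrow(x$removed_cells), "cells; kept",
      x$kept_dims[1], "x", x$kept_dims[2], "\n")
  invisible(x)
}

#' Default symbol rules for mitochondrial/ribosomal gene removal
#'
#' Case-sensitive mouse symbol prefixes: `mt-` for mitochondrial genes and
#' `Rps`/`Rpl`/`Mrps`/`Mrpl` for (mitochondrial) ribosomal protein genes.
#' @export
default_strip_rules <- function() {
  list(mito_prefixes = "mt-",
       ribo_prefixes = c("Rps", "Rpl", "Mrps", "Mrpl"),
       drop_unannotated = TRUE)
}

#' Remove mitochondrial, ribosomal and unannotated genes
#'
#' Genes whose symbol matches a mito/ribo prefix rule, or whose symbol is
#' empty (no current annotation), are removed. Run before the cell filter
#' so per-cell totals are computed over the remaining genes.
#'
#' @param counts a [count_matrix] with gene symbols
#' @param rules list as from [default_strip_rules()]
#' @return list with `counts` (filtered) and `report` (a qc_report)
#' @export
strip_gene_classes <- function(counts, rules = default_strip_rules()) {
  sym <- counts$gene_symbols
  starts_with_any <- function(x, prefixes) {
    hit <- rep(FALSE, length(x))
    for (p in prefixes) hit <- hit | startsWith(x, p)
    hit
  }
  mito <- starts_with_any(sym, rules$mito_prefixes)
  ribo <- starts_with_any(sym, rules$ribo_prefixes)
  unann <- if (isTRUE(rules$drop_unannotated)) !nzchar(sym) else
    rep(FALSE, length(sym))
  drop <- mito | ribo | unann
  reason <- ifelse(mito, "mitochondrial",
                   ifelse(ribo, "ribosomal", "unannotated"))[drop]
  kept <- counts[!drop, ]
  list(counts = kept,
       report = qc_report(removed_genes = counts$gene_ids[drop],
                          gene_reasons = reason,
                          kept_dims = dim(kept)))
}

#' Drop low-coverage cells
#'
#' A cell is dropped if fewer than `min_read_pairs` read pairs were
#' assigned to the (remaining) genes or fewer than `min_detected_genes`
#' genes were detected (raw count >= 1). "Fewer than" is a strict
#' inequality: a cell exactly at both thresholds is kept.
#'
#' @param counts a [count_matrix] (after [strip_gene_classes()])
#' @param th a [qc_thresholds]
#' @param relaxed use the relaxed threshold pair
#' @return list with `counts` and `report`
#' @export
filter_cells <- function(counts, th = qc_thresholds(), relaxed = FALSE) {
  min_total <- if (relaxed) th$relaxed_min_read_pairs else th$min_read_pairs
  min_genes <- if (relaxed) th$relaxed_min_detected_genes else
    th$min_detected_genes
  totals <- colSums(counts$counts)
  detected <- colSums(counts$counts >= 1)
  low_total <- totals < min_total
  low_genes <- detected < min_genes
  drop <- low_total | low_genes
  reason <- ifelse(low_total & low_genes, "low_total+low_detected",
                   ifelse(low_total, "low_total", "low_detected"))[drop]
  kept <- counts[, !drop]
  list(counts = kept,
       report = qc_report(removed_cells = counts$sample_ids[drop],
                          cell_reasons = reason,
                          kept_dims = dim(kept)))
}

#' Drop genes not achieving a CPM floor in enough cells
#'
#' Keeps genes with CPM >= `min_cpm` in at least `min_cells_at_cpm` cells,
#' with CPM computed on the library sizes of the cells present (run
#' [filter_cells()] first; zero-library cells are an error).
#'
#' @param counts a [count_matrix]
#' @param th a [qc_thresholds]
#' @return list with `counts` and `report`
#' @export
filter_genes_cpm <- function(counts, th = qc_thresholds()) {
  if (ncol(counts$counts) < 1) stop("no cells")
  libsize <- colSums(counts$counts)
  if (any(libsize == 0))
    stop("zero library size cell present; run filter_cells first")
  cpm <- sweep(counts$counts, 2, libsize, `/`) * 1e6
  n_ok <- rowSums(cpm >= th$min_cpm)
  drop <- n_ok < th$min_cells_at_cpm
  kept <- counts[!drop, ]
  list(counts = kept,
       report = qc_report(removed_genes = counts$gene_ids[drop],
                          gene_reasons = rep("low_cpm", sum(drop)),
                          kept_dims = dim(kept)))
}

#' Remove cells not expressing housekeeping genes (qPCR Ct matrix)
#'
#' For multiplex qPCR data: cells in which any housekeeping gene (e.g.
#' ACTB, GAPDH) is undetected (Ct >= `undetected_ct`; Ct of 40 or more
#' means no expression) are removed.
#'
#' @param ct numeric gene x cell matrix of Ct values with dimnames
#' @param housekeeping character vector of housekeeping gene rows
#' @param undetected_ct Ct at or above which a gene counts as undetected
#' @return list with `ct` (filtered matrix) and `report`
#' @export
filter_cells_housekeeping <- function(ct, housekeeping,
                                      undetected_ct = 40) {
  missing <- setdiff(housekeeping, rownames(ct))
  if (length(missing))
    stop("housekeeping gene(s) absent from Ct table: ",
         paste(missing, collapse = ", "))
  hk <- ct[housekeeping, , drop = FALSE]
  drop <- apply(hk >= undetected_ct, 2, any)
  kept <- ct[, !drop, drop = FALSE]
  list(ct = kept,
       report = qc_report(removed_cells = colnames(ct)[drop],
                          cell_reasons = rep("housekeeping_undetected",
                                             sum(drop)),
                          kept_dims = dim(kept)))
}
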