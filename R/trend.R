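#' Monotone-trend statistic for an intermediate population
#'
#' Runs a one-way NB likelihood-ratio test across the three cell groups
#' (LP, intermediate, ML); among genes below `fdr_cut`, computes the
#' linear-scale (mean CPM) group means and calls a gene monotone when the
#' intermediate mean lies within `[min(LP, ML) - eps, max(LP, ML) + eps]`
#' (inclusive betweenness, direction-symmetric). Reports the fraction of
#' DE genes that are monotone. A log-scale mode averages log2-CPM instead.
#'
#' @param counts a [count_matrix]
#' @param labels per-sample labels (default `sample_meta$group`)
#' @param lp,int,ml names of the progenitor, intermediate and mature labels
#' @param fdr_cut FDR cut for the DE universe (default 0.01)
#' @param eps betweenness slack on the linear mean scale (default 0)
#' @param disp optional `dispersion_model` (estimated if missing)
#' @param scale `"linear"` (default) or `"log"` group means
#' @return a `monotone_trend_result`: list with `n_de_genes`,
#'   `n_monotone`, `fraction_monotone` and a `per_gene` data.frame (means,
#'   `monotone`, `direction`)
#' @export
monotone_fraction <- function(counts, labels = NULL, lp = "LP",
                              int = "LumInt", ml = "ML",
                              fdr_cut = 0.01, eps = 0, disp = NULL,
                              scale = c("linear", "log")) {
  scale <- match.arg(scale)
  f <- as_group_factor(counts, labels)
  need <- c(lp, int, ml)
  if (!all(need %in% levels(f)))
    stop("labels must contain groups ", paste(need, collapse = ", "))
  keep <- f %in% need
  if (any(table(factor(f[keep], levels = need)) == 0)) stop("empty group")
  sub <- counts[, which(keep)]
  fsub <- factor(as.character(f[keep]), levels = need)
  if (is.null(disp)) disp <- estimate_dispersions(sub, fsub)
  de <- lrt_de(sub, fsub, disp)

  cpm <- sweep(sub$counts, 2, colSums(sub$counts), `/`) * 1e6
  if (scale == "log") cpm <- log2(cpm + 0.5)
  gmean <- vapply(need, function(g)
    rowMeans(cpm[, fsub == g, drop = FALSE]), numeric(nrow(cpm)))
  colnames(gmean) <- c("mean_lp", "mean_int", "mean_ml")

  lo <- pmin(gmean[, 1], gmean[, 3]) - eps
  hi <- pmax(gmean[, 1], gmean[, 3]) + eps
  monotone <- gmean[, 2] >= lo & gmean[, 2] <= hi
  direction <- ifelse(!monotone, "non-monotone",
                      ifelse(gmean[, 3] >= gmean[, 1], "up", "down"))
  per_gene <- data.frame(gene_id = sub$gene_ids, gmean,
                         fdr = de$fdr, de = de$fdr < fdr_cut,
                         monotone = unname(monotone),
                         direction = unname(direction), row.names = NULL)
  de_idx <- per_gene$de
  n_de <- sum(de_idx)
  n_mono <- sum(per_gene$monotone[de_idx])
  structure(list(n_de_genes = n_de, n_monotone = n_mono,
                 fraction_monotone = if (n_de > 0) n_mono / n_de else NA_real_,
                 per_gene = per_gene),
            class = "monotone_trend_result")
}

#' @export
#' @method print monotone_trend_result
print.monotone_trend_result <- function(x, ...) {
  cat("monotone_trend_result:", x$n_monotone, "of", x$n_de_genes,
      "DE genes monotone (",
      if (is.na(x$fraction_monotone)) "NA" else
        sprintf("%.1f%%", 100 * x$fraction_monotone), ")\n")
  invisible(x)
}

#' Genes elevated in the intermediate population
#'
#' Genes whose mean expression in the intermediate population is at least
#' `ratio` times the mean of BOTH parents (linear CPM scale); `ratio =
#' 1.2` is the "at least 20% higher" rule. By default the search is
#' restricted to the DE universe at `fdr_cut` (set `universe = "all"` to
#' use every gene).
#'
#' @inheritParams monotone_fraction
#' @param ratio required mean ratio vs each parent (default 1.2)
#' @param universe `"de"` (default) or `"all"`
#' @return an `elevated_intermediate_result`: list with `genes`
#'   (data.frame gene_id, mean columns, `ratio_vs_lp`, `ratio_vs_ml`) and
#'   `threshold`
#' @export
elevated_intermediate_genes <- function(counts, labels = NULL, lp = "LP",
                                        int = "LumInt", ml = "ML",
                                        ratio = 1.2,
                                        universe = c("de", "all"),
                                        fdr_cut = 0.01, disp = NULL) {
  universe <- match.arg(universe)
  mt <- monotone_fraction(counts, labels, lp = lp, int = int, ml = ml,
                          fdr_cut = fdr_cut, disp = disp)
  pg <- mt$per_gene
  if (universe == "de") pg <- pg[pg$de, , drop = FALSE]
  hit <- pg$mean_int >= ratio * pg$mean_lp &
         pg$mean_int >= ratio * pg$mean_ml
  genes <- pg[hit, c("gene_id", "mean_lp", "mean_int", "mean_ml")]
  genes$ratio_vs_lp <- genes$mean_int / genes$mean_lp
  genes$ratio_vs_ml <- genes$mean_int / genes$mean_ml
  rownames(genes) <- NULL
  structure(list(genes = genes, threshold = ratio),
            class = "elevated_intermediate_result")
}

#' @export
#' @method print elevated_intermediate_result
print.elevated_intermediate_result <- function(x, ...) {
  cat("elevated_intermediate_result:", nrow(x$genes),
      "genes at ratio >=", x$threshold, "\n")
  invisible(x)
}

#' Flag cell clusters with elevated cell-cycle expression
#'
#' Each cell's score is its mean standardized expression over the
#' cell-cycle genes; a cluster is flagged when its mean score exceeds the
#' all-cell mean score by more than `z_margin` standard deviations of the
#' cluster means.
#'
#' @param expr an [expr_matrix], expected `standardized`
#' @param cycle_genes character vector of cell-cycle gene ids
#' @param cluster_labels per-cell cluster labels
#' @param z_margin margin in SDs of cluster means (default 0.5)
#' @return list with `cell_scores` (named numeric) and `clusters`
#'   (data.frame cluster, mean_score, flagged)
#' @export
cell_cycle_flag <- function(expr, cycle_genes, cluster_labels,
                            z_margin = 0.5) {
  g <- intersect(cycle_genes, rownames(expr$values))
  if (!length(g)) stop("no cell-cycle genes present in the matrix")
  score <- colMeans(expr$values[g, , drop = FALSE])
  f <- factor(cluster_labels, levels = unique(cluster_labels))
  cl_mean <- tapply(score, f, mean)
  sd_cl <- stats::sd(cl_mean)
  if (is.na(sd_cl)) sd_cl <- 0
  margin <- if (sd_cl == 0) 0 else z_margin * sd_cl
  flagged <- cl_mean > mean(score) + margin
  list(cell_scores = score,
       clusters = data.frame(cluster = names(cl_mean),
                             mean_score = as.numeric(cl_mean),
                             flagged = as.logical(flagged),
                             row.names = NULL))
}
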