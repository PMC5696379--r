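#' Per-cell ternary lineage composition scores
#'
#' For each cell and each of the three signature classes, the raw score is
#' the mean over the class's genes of the expression above `floor`
#' (`max(0, expr - floor)`), computed on quantile-normalized log2-CPM.
#' Proportions are the raw scores normalized to sum to 1; a cell with all
#' raw scores 0 is degenerate and gets (1/3, 1/3, 1/3). Using the per-set
#' mean (not the sum) removes signature-size bias. Optionally the raw
#' score can instead count detected genes above the floor
#' (`method = "count"`).
#'
#' @param expr an [expr_matrix], expected `quantile_log2cpm`
#' @param sigs a [signature_set] (or named list) with exactly 3 sets
#' @param floor expression floor; default is the matrix-wide median
#' @param method `"mean"` (default) or `"count"` of genes above floor
#' @return data.frame with `sample_id`, one proportion column per class,
#'   `raw.<class>` columns, `label` (argmax class) and `degenerate`
#' @export
ternary_cell_scores <- function(expr, sigs, floor = NULL,
                                method = c("mean", "count")) {
  method <- match.arg(method)
  sets <- if (inherits(sigs, "signature_set")) sigs$sets else sigs
  if (length(sets) != 3) stop("ternary scoring needs exactly 3 sets")
  x <- expr$values
  if (is.null(floor)) floor <- stats::median(x)
  raw <- matrix(0, ncol(x), 3,
                dimnames = list(colnames(x), names(sets)))
  for (nm in names(sets)) {
    g <- intersect(sets[[nm]], rownames(x))
    if (!length(g))
      stop("signature set '", nm, "' has no genes in the expression matrix")
    ex <- pmax(x[g, , drop = FALSE] - floor, 0)
    raw[, nm] <- if (method == "mean") colMeans(ex) else colMeans(ex > 0)
  }
  tot <- rowSums(raw)
  degenerate <- tot == 0
  prop <- raw / ifelse(tot == 0, 1, tot)
  prop[degenerate, ] <- 1 / 3
  label <- names(sets)[max.col(prop, ties.method = "first")]
  out <- data.frame(sample_id = colnames(x), prop, check.names = FALSE)
  rawdf <- as.data.frame(raw)
  names(rawdf) <- paste0("raw.", names(sets))
  out <- cbind(out, rawdf)
  out$label <- label
  out$degenerate <- unname(degenerate)
  rownames(out) <- NULL
  out
}

#' Classify cells from ternary scores
#'
#' The label is the argmax proportion (ties broken by the fixed class
#' order of the score columns); degenerate cells are labelled
#' `"unclassified"`. If `intermediate_band` is set, cells whose two
#' luminal-class proportions differ by less than the band and both exceed
#' the remaining (basal) proportion are labelled `intermediate_label`.
#'
#' @param scores data.frame from [ternary_cell_scores()]
#' @param intermediate_band band width `b`, or `NULL` (off, the default)
#' @param intermediate_pair the two class names compared by the band rule
#'   (default: second and third score columns)
#' @param intermediate_label label for banded cells (default "Lum Int")
#' @return character vector of labels, one per row of `scores`
#' @export
classify_cells <- function(scores, intermediate_band = NULL,
                           intermediate_pair = NULL,
                           intermediate_label = "Lum Int") {
  classes <- setdiff(names(scores),
                     c("sample_id", "label", "degenerate",
                       grep("^raw\\.", names(scores), value = TRUE)))
  if (length(classes) != 3) stop("expected 3 proportion columns")
  prop <- as.matrix(scores[, classes])
  label <- classes[max.col(prop, ties.method = "first")]
  label[scores$degenerate] <- "unclassified"
  if (!is.null(intermediate_band)) {
    if (is.null(intermediate_pair)) intermediate_pair <- classes[2:3]
    other <- setdiff(classes, intermediate_pair)
    a <- prop[, intermediate_pair[1]]
    b <- prop[, intermediate_pair[2]]
    o <- prop[, other]
    band <- abs(a - b) < intermediate_band & a > o & b > o
    label[band & !scores$degenerate] <- intermediate_label
  }
  label
}

#' Per-gene expression composition across three stages
#'
#' For each gene, expression is averaged over all cells at each stage on
#' the linear scale (log-normalized input is exponentiated first) and the
#' three stage means are normalized to proportions. Genes with zero mean
#' everywhere are degenerate and get (1/3, 1/3, 1/3).
#'
#' @param expr an [expr_matrix]
#' @param groups per-sample stage labels with exactly 3 levels
#' @return data.frame with `gene_id`, one proportion column per stage, and
#'   `degenerate`
#' @export
ternary_gene_composition <- function(expr, groups) {
  f <- factor(groups, levels = unique(groups))
  if (nlevels(f) != 3) stop("need exactly 3 stages")
  if (any(table(f) == 0)) stop("empty stage")
  x <- expr$values
  if (expr$normalization %in% c("log2cpm", "log2rpkm", "quantile_log2cpm"))
    x <- 2^x
  means <- vapply(levels(f),
                  function(g) rowMeans(x[, f == g, drop = FALSE]),
                  numeric(nrow(x)))
  tot <- rowSums(means)
  degenerate <- tot == 0
  prop <- means / ifelse(tot == 0, 1, tot)
  prop[degenerate, ] <- 1 / 3
  out <- data.frame(gene_id = rownames(x), prop, check.names = FALSE)
  out$degenerate <- unname(degenerate)
  rownames(out) <- NULL
  out
}

#' Detect mixed-lineage (lineage-primed) cells in a sorted population
#'
#' For each cell of the sorted host class, counts the foreign-signature
#' genes expressed above `detect_log2rpkm` (log2-RPKM scale). A cell is
#' called mixed when at least `min_foreign_genes` foreign genes are
#' detected AND the cell remains host-like: its host raw signature score
#' (as in [ternary_cell_scores()]) exceeds `host_dominance` times the
#' foreign raw score.
#'
#' @param expr an [expr_matrix], expected `log2rpkm`
#' @param host_class name of the host signature set
#' @param sigs a [signature_set] (or named list) containing the host set
#'   and at least one foreign set (foreign = union of the others)
#' @param min_foreign_genes detected foreign genes required (default 3)
#' @param detect_log2rpkm detection threshold on log2-RPKM
#'   (default `log2(5)`, i.e. RPKM > 5)
#' @param host_dominance host-dominance factor (default 1)
#' @param floor floor for the raw scores (default matrix-wide median)
#' @return data.frame with `sample_id`, `host_class`,
#'   `n_foreign_detected`, `foreign_genes` (comma-joined), `host_score`,
#'   `foreign_score`, `is_mixed`
#' @export
detect_mixed_lineage <- function(expr, host_class, sigs,
                                 min_foreign_genes = 3,
                                 detect_log2rpkm = log2(5),
                                 host_dominance = 1,
                                 floor = NULL) {
  sets <- if (inherits(sigs, "signature_set")) sigs$sets else sigs
  if (!host_class %in% names(sets))
    stop("host class '", host_class, "' not in signature sets")
  foreign_set <- unique(unlist(sets[setdiff(names(sets), host_class)],
                               use.names = FALSE))
  host_set <- sets[[host_class]]
  if (!length(foreign_set) || identical(sort(host_set), sort(foreign_set)))
    stop("host and foreign signature sets must differ")
  x <- expr$values
  hg <- intersect(host_set, rownames(x))
  fg <- intersect(foreign_set, rownames(x))
  if (!length(hg) || !length(fg))
    stop("signature genes absent from the expression matrix")
  if (is.null(floor)) floor <- stats::median(x)

  det <- x[fg, , drop = FALSE] > detect_log2rpkm
  n_det <- colSums(det)
  genes <- apply(det, 2, function(z) paste(fg[z], collapse = ","))
  host_score <- colMeans(pmax(x[hg, , drop = FALSE] - floor, 0))
  foreign_score <- colMeans(pmax(x[fg, , drop = FALSE] - floor, 0))
  is_mixed <- n_det >= min_foreign_genes &
    host_score > host_dominance * foreign_score
  data.frame(sample_id = colnames(x), host_class = host_class,
             n_foreign_detected = unname(n_det),
             foreign_genes = unname(genes),
             host_score = unname(host_score),
             foreign_score = unname(foreign_score),
             is_mixed = unname(is_mixed), row.names = NULL)
}

#' Flag cells expressing a marker above a linear-scale threshold
#'
#' For log-scale input the comparison is on `2^value`; the comparison is
#' strict (`> threshold`), so a cell exactly at the threshold is not
#' flagged. The canonical use is flagging CD55-positive cells at RPKM > 40.
#'
#' @param expr an [expr_matrix] on an RPKM-compatible normalization
#' @param gene gene id
#' @param threshold_linear linear-scale threshold (e.g. 40 RPKM)
#' @return named logical vector, one entry per cell
#' @export
flag_marker_positive <- function(expr, gene, threshold_linear) {
  if (!gene %in% rownames(expr$values))
    stop("gene '", gene, "' absent from the expression matrix")
  v <- expr$values[gene, ]
  if (expr$normalization %in% c("log2cpm", "log2rpkm", "quantile_log2cpm"))
    v <- 2^v
  v > threshold_linear
}
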