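#' Pairwise leading log-fold-change distances between cells
#'
#' For each pair of cells the per-gene log2 expression differences are
#' computed, the `k_top` largest absolute differences selected (recomputed
#' for every pair), and the distance is their root mean square. With
#' `k_top >= n_genes` this is the plain RMS over all genes. The per-pair
#' selection runs in compiled code.
#'
#' @param expr an [expr_matrix], expected `log2cpm`
#' @param k_top number of top fold changes per pair (default 500)
#' @return a `dist_matrix`: symmetric matrix with zero diagonal plus
#'   `method`/`k_top` attributes
#' @export
leading_logfc_distances <- function(expr, k_top = 500) {
  if (k_top < 1) stop("k_top must be >= 1")
  x <- expr$values
  if (ncol(x) < 2) stop("need >= 2 cells")
  d <- pairwise_leading_rms(x, as.integer(k_top))
  dimnames(d) <- list(colnames(x), colnames(x))
  structure(d, method = "leading_logfc", k_top = k_top,
            class = c("dist_matrix", "matrix", "array"))
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers `-D^2/2`, eigendecomposes, and returns the top
#' coordinates scaled by the square root of the eigenvalues (negative
#' eigenvalues clamped to zero). Axis signs follow a fixed convention (the
#' largest-magnitude loading on each axis is positive) so output is
#' reproducible across platforms.
#'
#' @param d a `dist_matrix` or symmetric distance matrix
#' @param dims number of dimensions (default 2; must be <= n-1)
#' @return n x dims coordinate matrix
#' @export
classical_mds <- function(d, dims = 2) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (dims > n - 1) stop("dims must be <= n - 1")
  b <- -0.5 * d^2
  b <- sweep(b, 1, rowMeans(b))
  b <- sweep(b, 2, colMeans(b))
  eig <- eigen((b + t(b)) / 2, symmetric = TRUE)
  lambda <- pmax(eig$values[seq_len(dims)], 0)
  coords <- eig$vectors[, seq_len(dims), drop = FALSE]
  for (a in seq_len(dims)) {
    v <- coords[, a]
    s <- sign(v[which.max(abs(v))])
    if (s < 0) coords[, a] <- -v
  }
  coords <- sweep(coords, 2, sqrt(lambda), `*`)
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("dim", seq_len(dims))
  coords
}

#' Hierarchical clustering of genes or cells by Euclidean distance
#'
#' Standardized input is expected when clustering genes (so Euclidean
#' distance compares expression patterns, not magnitudes). Agglomeration
#' uses the stated linkage; ties are broken deterministically by input
#' order.
#'
#' @param expr an [expr_matrix]
#' @param axis cluster `"genes"` (rows) or `"cells"` (columns)
#' @param linkage `"complete"` (default), `"average"` or `"ward"`
#' @return a `dendrogram_result`: list with the `hclust` object (`tree`),
#'   `leaf_order`, `labels`, `linkage`, `axis`
#' @export
hcluster <- function(expr, axis = c("genes", "cells"),
                     linkage = c("complete", "average", "ward")) {
  axis <- match.arg(axis)
  linkage <- match.arg(linkage)
  m <- if (axis == "genes") expr$values else t(expr$values)
  if (nrow(m) < 2) stop("need >= 2 items to cluster")
  method <- if (linkage == "ward") "ward.D2" else linkage
  hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                      method = method)
  structure(list(tree = hc, leaf_order = hc$order,
                 labels = rownames(m), linkage = linkage, axis = axis),
            class = "dendrogram_result")
}

#' @export
#' @method print dendrogram_result
print.dendrogram_result <- function(x, ...) {
  cat("dendrogram_result:", length(x$labels), x$axis, "items,",
      x$linkage, "linkage\n")
  invisible(x)
}

#' Cut a dendrogram into k clusters
#'
#' @param tree a `dendrogram_result` from [hcluster()]
#' @param k number of clusters, `1 <= k <= n`
#' @return named integer cluster labels (stable across runs)
#' @export
cut_clusters <- function(tree, k) {
  n <- length(tree$labels)
  if (k < 1 || k > n) stop("k must be in [1, ", n, "]")
  stats::cutree(tree$tree, k = k)
}
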