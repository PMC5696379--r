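#' Counts per million
#'
#' @param counts a [count_matrix]; every library size must be positive
#' @return an [expr_matrix] with `normalization = "cpm"`
#' @export
to_cpm <- function(counts) {
  libsize <- colSums(counts$counts)
  if (any(libsize <= 0)) stop("zero library size")
  expr_matrix(sweep(counts$counts, 2, libsize, `/`) * 1e6, "cpm")
}

#' log2 counts per million with a prior count
#'
#' `log2((count + prior) / (libsize + 2*prior) * 1e6)`. The prior guards
#' against log of zero; the library size is inflated by twice the prior so
#' the transform stays monotone in the count at fixed library size.
#'
#' @param counts a [count_matrix]
#' @param prior prior count, must be > 0 (default 0.5)
#' @return an [expr_matrix] with `normalization = "log2cpm"`
#' @export
to_log2cpm <- function(counts, prior = 0.5) {
  if (prior <= 0) stop("prior must be > 0")
  libsize <- colSums(counts$counts)
  if (any(libsize <= 0)) stop("zero library size")
  v <- log2(sweep(counts$counts + prior, 2, libsize + 2 * prior, `/`) * 1e6)
  expr_matrix(v, "log2cpm", prior_count = prior)
}

#' log2 reads per kilobase per million with a library-size-scaled prior
#'
#' The prior count is scaled per column proportionally to
#' `libsize / mean(libsize)` and the effective library size is inflated by
#' twice the scaled prior, so columns of equal depth are treated
#' identically and the offset is comparable across depths:
#' `log2((count + prior_j) / (libsize_j + 2*prior_j) * 1e9 / length_bp)`.
#' A plain unscaled mode is available via `scale_prior = FALSE`.
#'
#' @param counts a [count_matrix] with gene lengths
#' @param prior prior count before scaling (default 5)
#' @param scale_prior scale the prior by relative library size (default
#'   TRUE)
#' @return an [expr_matrix] with `normalization = "log2rpkm"`
#' @export
to_log2rpkm <- function(counts, prior = 5, scale_prior = TRUE) {
  if (prior <= 0) stop("prior must be > 0")
  if (is.null(counts$gene_lengths))
    stop("gene lengths are required for RPKM")
  libsize <- colSums(counts$counts)
  if (any(libsize <= 0)) stop("zero library size")
  prior_j <- if (scale_prior) prior * libsize / mean(libsize)
             else rep(prior, length(libsize))
  v <- sweep(counts$counts, 2, prior_j, `+`)
  v <- sweep(v, 2, libsize + 2 * prior_j, `/`) * 1e9
  v <- log2(sweep(v, 1, counts$gene_lengths, `/`))
  expr_matrix(v, "log2rpkm", prior_count = prior)
}

#' Quantile normalization across columns
#'
#' After normalization every column's sorted values equal the across-column
#' mean of sorted values (the reference distribution); tied values within a
#' column receive the mean of the reference values over their rank span.
#'
#' @param expr an [expr_matrix] with at least 2 columns
#' @return an [expr_matrix]; `log2cpm` input is tagged `quantile_log2cpm`
#' @export
quantile_normalize <- function(expr) {
  x <- expr$values
  if (ncol(x) < 2) stop("quantile normalization needs >= 2 columns")
  ref <- rowMeans(apply(x, 2, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    o <- order(x[, j])
    sorted <- x[o, j]
    grp <- cumsum(c(TRUE, diff(sorted) != 0))
    span_mean <- vapply(split(seq_along(sorted), grp),
                        function(ix) mean(ref[ix]), 0)
    out[o, j] <- span_mean[grp]
  }
  tag <- if (expr$normalization == "log2cpm") "quantile_log2cpm"
         else expr$normalization
  expr_matrix(out, tag, prior_count = expr$prior_count)
}

#' Standardize each gene to mean 0 and SD 1
#'
#' Row SD uses the n-1 denominator. Constant rows cannot be standardized;
#' they are set to 0 and flagged in `constant_genes`.
#'
#' @param expr an [expr_matrix] with at least 2 samples
#' @return an [expr_matrix] with `normalization = "standardized"`
#' @export
standardize_genes <- function(expr) {
  x <- expr$values
  if (ncol(x) < 2) stop("standardization needs >= 2 samples")
  mu <- rowMeans(x)
  sdv <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1))
  const <- sdv == 0
  sdv[const] <- 1
  z <- (x - mu) / sdv
  z[const, ] <- 0
  expr_matrix(z, "standardized",
              constant_genes = stats::setNames(const, rownames(x)))
}
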