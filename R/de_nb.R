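# Negative-binomial differential expression.
#
# Self-contained machinery: one-way NB GLMs with log link and library-size
# offsets fitted by Newton scoring (equivalent to IRLS for an intercept per
# group), adjusted-profile-likelihood dispersion estimation with weighted
# shrinkage, likelihood-ratio tests, and fold-change-threshold (TREAT-style)
# tests against a shifted null.

nb_loglik_rows <- function(y, mu, phi) {
  # phi recycles down columns (per-gene dispersion)
  rowSums(stats::dnbinom(y, mu = mu, size = 1 / phi, log = TRUE))
}

# Fit per-gene intercepts beta with mu = exp(beta + offset). `y` is genes x
# samples, `offs` length-ncol offsets, `phi` per-gene dispersions. A ridge
# of 1e-6 on the intercept keeps all-zero groups finite.
fit_nb_mean <- function(y, offs, phi, max_iter = 50L, tol = 1e-10,
                        ridge = 1e-6) {
  n <- nrow(y)
  sum_eo <- sum(exp(offs))
  beta <- log((rowSums(y) + 0.1) / sum_eo)
  converged <- rep(FALSE, n)
  offm <- matrix(offs, n, length(offs), byrow = TRUE)
  for (it in seq_len(max_iter)) {
    mu <- exp(beta + offm)
    w <- 1 + phi * mu
    score <- rowSums((y - mu) / w) - ridge * beta
    info <- rowSums(mu / w) + ridge
    delta <- score / info
    delta <- pmin(pmax(delta, -3), 3)
    beta <- beta + delta
    converged <- abs(delta) < tol
    if (all(converged)) break
  }
  mu <- exp(beta + offm)
  w <- 1 + phi * mu
  list(beta = beta,
       ll = nb_loglik_rows(y, mu, phi),
       info = rowSums(mu / w),
       converged = converged)
}

as_group_factor <- function(counts, groups) {
  if (is.null(groups)) groups <- sample_groups(counts)
  if (length(groups) != ncol(counts$counts))
    stop("groups length does not match samples")
  if (is.factor(groups)) droplevels(groups) else
    factor(groups, levels = unique(groups))
}

# Fit the one-way layout: per-group intercepts plus the pooled null fit.
fit_oneway <- function(y, offs, phi, f) {
  lev <- levels(f)
  beta <- matrix(NA_real_, nrow(y), length(lev),
                 dimnames = list(rownames(y), lev))
  ll <- 0
  cr <- 0
  conv <- rep(TRUE, nrow(y))
  for (g in lev) {
    j <- which(f == g)
    fit <- fit_nb_mean(y[, j, drop = FALSE], offs[j], phi)
    beta[, g] <- fit$beta
    ll <- ll + fit$ll
    cr <- cr + 0.5 * log(fit$info + 1e-300)
    conv <- conv & fit$converged
  }
  list(beta = beta, ll = ll, cr = cr, converged = conv)
}

#' Estimate NB dispersions by adjusted profile likelihood
#'
#' The common dispersion maximizes the average Cox-Reid adjusted profile
#' likelihood (APL) over genes, located on a 21-point log-spaced grid over
#' 0.001-10 and refined by golden-section search. Tagwise dispersions
#' maximize the weighted likelihood `APL_g(phi) + shrink_weight *
#' mean_APL(phi)` (grid argmax with parabolic refinement on log-phi),
#' shrinking each gene toward the common value with `shrink_weight` prior
#' observations; `shrink_weight = Inf` returns the common value for every
#' gene.
#'
#' @param counts a [count_matrix]
#' @param groups per-sample labels (default: `sample_meta$group`)
#' @param shrink_weight prior observations for tagwise shrinkage
#' @param grid dispersion grid (log-spaced)
#' @param lib_sizes optional known library sizes used as offsets (default:
#'   column sums)
#' @return a `dispersion_model` with `common_phi`, `tagwise_phi`,
#'   `shrink_weight`
#' @export
estimate_dispersions <- function(counts, groups = NULL, shrink_weight = 10,
                                 grid = 10^seq(-3, 1, length.out = 21),
                                 lib_sizes = NULL) {
  y <- counts$counts
  if (all(y == 0)) stop("all-zero count matrix")
  f <- as_group_factor(counts, groups)
  offs <- log(if (is.null(lib_sizes)) colSums(y) else lib_sizes)
  n <- nrow(y)

  apl_at <- function(phi_scalar) {
    fit <- fit_oneway(y, offs, rep(phi_scalar, n), f)
    fit$ll - fit$cr
  }
  apl <- vapply(grid, apl_at, numeric(n))   # genes x grid

  mean_apl <- colMeans(apl)
  i0 <- which.max(mean_apl)
  lo <- log(grid[max(1, i0 - 1)]); hi <- log(grid[min(length(grid), i0 + 1)])
  gold <- function(fn, lo, hi, iter = 25) {
    gr <- (sqrt(5) - 1) / 2
    a <- lo; b <- hi
    c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
    f1 <- fn(c1); f2 <- fn(c2)
    for (i in seq_len(iter)) {
      if (f1 > f2) { b <- c2; c2 <- c1; f2 <- f1
        c1 <- b - gr * (b - a); f1 <- fn(c1)
      } else { a <- c1; c1 <- c2; f1 <- f2
        c2 <- a + gr * (b - a); f2 <- fn(c2) }
    }
    (a + b) / 2
  }
  common <- exp(gold(function(lphi) mean(apl_at(exp(lphi))), lo, hi))

  if (is.infinite(shrink_weight)) {
    tag <- rep(common, n)
  } else {
    wl <- apl + shrink_weight * matrix(mean_apl, n, length(grid),
                                       byrow = TRUE)
    imax <- max.col(wl, ties.method = "first")
    lg <- log(grid)
    tag <- numeric(n)
    for (g in seq_len(n)) {
      i <- imax[g]
      if (i == 1 || i == length(grid)) { tag[g] <- grid[i]; next }
      x <- lg[(i - 1):(i + 1)]
      v <- wl[g, (i - 1):(i + 1)]
      h <- (x[3] - x[1]) / 2
      denom <- v[1] - 2 * v[2] + v[3]
      tag[g] <- if (denom >= 0) grid[i] else
        exp(x[2] + 0.5 * h * (v[1] - v[3]) / denom)
    }
  }
  structure(list(common_phi = common,
                 tagwise_phi = stats::setNames(tag, rownames(y)),
                 shrink_weight = shrink_weight),
            class = "dispersion_model")
}

#' @export
#' @method print dispersion_model
print.dispersion_model <- function(x, ...) {
  cat("dispersion_model: common phi =", signif(x$common_phi, 4),
      "; tagwise range", signif(min(x$tagwise_phi), 3), "-",
      signif(max(x$tagwise_phi), 3), "\n")
  invisible(x)
}

disp_vector <- function(disp, gene_ids) {
  if (inherits(disp, "dispersion_model")) {
    phi <- disp$tagwise_phi[gene_ids]
    if (anyNA(phi)) phi <- rep(disp$common_phi, length(gene_ids))
    unname(phi)
  } else if (is.numeric(disp)) {
    rep_len(disp, length(gene_ids))
  } else stop("disp must be a dispersion_model or numeric")
}

#' NB likelihood-ratio test for differential expression
#'
#' Per gene, a one-way NB GLM with log link and log library-size offsets:
#' the full model fits one mean per group, the null a common mean; the
#' statistic `2*(ll_full - ll_null)` is referred to a chi-square with
#' `n_groups - 1` degrees of freedom. Supports any number of groups (the
#' multi-group form ranks genes across developmental stages). Genes whose
#' fits fail to converge are flagged with p = 1.
#'
#' @param counts a [count_matrix]
#' @param groups per-sample labels (default `sample_meta$group`)
#' @param disp a `dispersion_model` or numeric dispersion(s)
#' @param lib_sizes optional known library sizes used as offsets (default:
#'   column sums)
#' @return data.frame with `gene_id`, `log2fc` (second over first group for
#'   two groups; max spread for more), `lr_stat`, `p`, `fdr`, `contrast`,
#'   `converged`, plus per-group mean columns `beta.<group>` (natural-log
#'   scale relative abundance)
#' @export
lrt_de <- function(counts, groups = NULL, disp, lib_sizes = NULL) {
  f <- as_group_factor(counts, groups)
  if (nlevels(f) < 2) stop("lrt_de needs >= 2 groups")
  y <- counts$counts
  offs <- log(if (is.null(lib_sizes)) colSums(y) else lib_sizes)
  phi <- disp_vector(disp, counts$gene_ids)

  full <- fit_oneway(y, offs, phi, f)
  null <- fit_nb_mean(y, offs, phi)
  stat <- pmax(2 * (full$ll - null$ll), 0)
  p <- stats::pchisq(stat, df = nlevels(f) - 1, lower.tail = FALSE)
  conv <- full$converged & null$converged
  if (any(!conv)) {
    warning(sum(!conv), " gene(s) failed to converge; p set to 1")
    p[!conv] <- 1
  }
  log2fc <- if (nlevels(f) == 2)
    (full$beta[, 2] - full$beta[, 1]) / log(2)
  else
    apply(full$beta, 1, function(b) diff(range(b))) / log(2)
  res <- data.frame(
    gene_id = counts$gene_ids,
    log2fc = unname(log2fc),
    lr_stat = unname(stat),
    p = unname(p),
    fdr = bh_adjust(unname(p)),
    contrast = paste(levels(f), collapse = "/"),
    converged = unname(conv),
    row.names = NULL)
  beta_df <- as.data.frame(full$beta / log(2))
  names(beta_df) <- paste0("beta.", levels(f))
  cbind(res, beta_df)
}

#' Fold-change-threshold (TREAT-style) NB test
#'
#' Tests `H0: |log2FC| <= log2(tau)` against `|log2FC| > log2(tau)` for two
#' groups. The likelihood ratio is computed against the shifted null at
#' each boundary (`log2FC = +/- log2(tau)`); the p-value combines the
#' upper tails of the signed square-root statistics from the nearer and
#' farther boundary, capped at 1, so the test is conservative when the true
#' effect sits exactly on the threshold. At `tau = 1` it reduces to the
#' two-group LRT.
#'
#' @param counts a [count_matrix]
#' @param groups per-sample labels with exactly 2 levels
#' @param disp a `dispersion_model` or numeric dispersion(s)
#' @param tau fold-change threshold, >= 1 (linear scale)
#' @param lib_sizes optional known library sizes used as offsets (default:
#'   column sums)
#' @return data.frame as [lrt_de()] plus `threshold_tau`
#' @export
treat_test <- function(counts, groups = NULL, disp, tau,
                       lib_sizes = NULL) {
  if (tau < 1) stop("tau must be >= 1")
  f <- as_group_factor(counts, groups)
  if (nlevels(f) != 2) stop("treat_test needs exactly 2 groups")
  y <- counts$counts
  offs <- log(if (is.null(lib_sizes)) colSums(y) else lib_sizes)
  phi <- disp_vector(disp, counts$gene_ids)

  full <- fit_oneway(y, offs, phi, f)
  b <- full$beta[, 2] - full$beta[, 1]          # natural log scale
  tn <- log(tau)
  s <- ifelse(b >= 0, 1, -1)
  is_b <- as.numeric(f == levels(f)[2])

  # constrained log-lik at a per-gene fixed log-FC c: the shift is folded
  # into the group-2 offsets, leaving a single free intercept per gene
  ll_constrained <- function(cvec) {
    llv <- numeric(nrow(y))
    for (cv in unique(cvec)) {
      idx <- which(cvec == cv)
      off2 <- offs + cv * is_b
      fit <- fit_nb_mean(y[idx, , drop = FALSE], off2, phi[idx])
      llv[idx] <- fit$ll
    }
    llv
  }

  ll_full <- full$ll
  lr_near <- pmax(2 * (ll_full - ll_constrained(s * tn)), 0)
  lr_far <- pmax(2 * (ll_full - ll_constrained(-s * tn)), 0)
  z_near <- sign(abs(b) - tn) * sqrt(lr_near)
  z_far <- sqrt(lr_far)
  p <- pmin(1, stats::pnorm(z_near, lower.tail = FALSE) +
                 stats::pnorm(z_far, lower.tail = FALSE))
  # the threshold test must never be more liberal than the point-null LRT;
  # floor at the LRT p-value (equality holds at tau = 1 by construction)
  lr0 <- pmax(2 * (ll_full - fit_nb_mean(y, offs, phi)$ll), 0)
  p <- pmax(p, stats::pchisq(lr0, df = 1, lower.tail = FALSE))
  data.frame(
    gene_id = counts$gene_ids,
    log2fc = unname(b / log(2)),
    lr_stat = unname(lr_near),
    p = unname(p),
    fdr = bh_adjust(unname(p)),
    contrast = paste(levels(f)[2], "vs", levels(f)[1]),
    threshold_tau = tau,
    converged = unname(full$converged),
    row.names = NULL)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Standard step-up adjusted p-values (monotone-enforced, capped at 1,
#' original order restored). `NaN`/`NA` inputs propagate with a warning and
#' the remaining values are adjusted among themselves.
#'
#' @param p numeric vector of p-values in `[0, 1]`
#' @return adjusted values, same length and order
#' @export
bh_adjust <- function(p) {
  na <- is.na(p)
  if (any(na)) warning("NaN/NA p-values propagated unadjusted")
  if (any(p[!na] < 0 | p[!na] > 1)) stop("p-values must lie in [0, 1]")
  out <- p
  out[!na] <- stats::p.adjust(p[!na], method = "BH")
  out
}

#' Default fold-change thresholds for three-way signature derivation
#'
#' 2 for basal vs LP and basal vs ML, 1.3 for LP vs ML. Contrast keys are
#' the two sorted labels joined by `_vs_`.
#' @export
default_tau_map <- function() {
  c(LP_vs_basal = 2, ML_vs_basal = 2, LP_vs_ML = 1.3)
}

contrast_key <- function(a, b)
  paste(sort(c(a, b), method = "radix"), collapse = "_vs_")

#' Derive lineage signature gene sets from bulk replicates
#'
#' A gene is cell-type specific if it is significantly upregulated in that
#' type against BOTH other types, each pairwise comparison run as a
#' fold-change-threshold test at its own tau with BH FDR below `fdr_cut`.
#' When a `biotype` vector is supplied only protein-coding genes are
#' considered.
#'
#' @param bulk a [count_matrix] of bulk replicates
#' @param celltypes per-sample labels with exactly 3 levels (default
#'   `sample_meta$group`)
#' @param tau_map named vector of fold-change thresholds keyed by
#'   `contrast_key` of the two labels (see [default_tau_map()])
#' @param fdr_cut FDR cut-off per comparison
#' @param disp optional `dispersion_model` (estimated if missing)
#' @param biotype optional per-gene biotype vector; only
#'   `keep_biotype` genes enter the analysis
#' @param keep_biotype biotype to retain (default "protein_coding")
#' @return a [signature_set] with one set per cell type and a `stats`
#'   data.frame of per-gene logFC/FDR (worst case over the two contrasts)
#' @export
derive_signatures <- function(bulk, celltypes = NULL,
                              tau_map = default_tau_map(),
                              fdr_cut = 0.05, disp = NULL,
                              biotype = NULL,
                              keep_biotype = "protein_coding") {
  if (!is.null(biotype)) {
    keep <- biotype == keep_biotype
    bulk <- bulk[keep, ]
  }
  f <- as_group_factor(bulk, celltypes)
  if (nlevels(f) != 3) stop("derive_signatures needs exactly 3 cell types")
  lev <- levels(f)
  if (is.null(disp)) disp <- estimate_dispersions(bulk, f)

  pairs <- utils::combn(lev, 2, simplify = FALSE)
  res <- list()
  for (pr in pairs) {
    key <- contrast_key(pr[1], pr[2])
    if (is.na(tau_map[key]))
      stop("no fold-change threshold for contrast ", key)
    j <- f %in% pr
    sub <- bulk[, which(j)]
    res[[key]] <- treat_test(sub, droplevels(f[j]), disp,
                             tau = unname(tau_map[key]))
  }
  sets <- list()
  stats_rows <- list()
  for (s in lev) {
    others <- setdiff(lev, s)
    ok <- rep(TRUE, length(bulk$gene_ids))
    lfc_s <- rep(Inf, length(bulk$gene_ids))
    fdr_s <- rep(0, length(bulk$gene_ids))
    for (t in others) {
      key <- contrast_key(s, t)
      r <- res[[key]]
      # orient logFC as s over t
      second <- sub("^(.*) vs .*$", "\\1", r$contrast[1])
      lfc <- if (second == s) r$log2fc else -r$log2fc
      ok <- ok & (r$fdr < fdr_cut) & (lfc > 0)
      lfc_s <- pmin(lfc_s, lfc)
      fdr_s <- pmax(fdr_s, r$fdr)
    }
    sets[[s]] <- bulk$gene_ids[ok]
    if (any(ok))
      stats_rows[[s]] <- data.frame(gene_id = bulk$gene_ids[ok], class = s,
                                    log2fc = lfc_s[ok], fdr = fdr_s[ok])
  }
  signature_set(sets,
                stats = if (length(stats_rows))
                  do.call(rbind, c(stats_rows, make.row.names = FALSE)),
                provenance = "derive_signatures")
}

#' Top-N lineage gene panels from a two-group comparison
#'
#' Runs the fold-change-threshold test at `tau`, splits significant genes
#' by the sign of the log fold change, and returns the top `n_top` of each
#' side ranked by ascending FDR, ties broken by descending |log2FC| then
#' lexical gene id.
#'
#' @param bulk a [count_matrix]
#' @param two_types per-sample labels with exactly 2 levels
#' @param tau fold-change threshold (default 3)
#' @param n_top panel size per side (default 200)
#' @param fdr_cut significance cut (default 0.05)
#' @param disp optional dispersion model
#' @return a [signature_set] with one panel per group
#' @export
top_lineage_panels <- function(bulk, two_types = NULL, tau = 3,
                               n_top = 200, fdr_cut = 0.05, disp = NULL) {
  f <- as_group_factor(bulk, two_types)
  if (nlevels(f) != 2) stop("top_lineage_panels needs exactly 2 groups")
  if (is.null(disp)) disp <- estimate_dispersions(bulk, f)
  r <- treat_test(bulk, f, disp, tau = tau)
  sig <- r[r$fdr < fdr_cut, , drop = FALSE]
  pick <- function(rows) {
    o <- order(rows$fdr, -abs(rows$log2fc), rows$gene_id)
    rows <- rows[o, , drop = FALSE]
    if (nrow(rows) < n_top)
      warning("only ", nrow(rows), " significant genes for a panel of ",
              n_top)
    utils::head(rows, n_top)
  }
  up2 <- pick(sig[sig$log2fc > 0, , drop = FALSE])  # up in second level
  up1 <- pick(sig[sig$log2fc < 0, , drop = FALSE])
  sets <- stats::setNames(list(up1$gene_id, up2$gene_id), levels(f))
  stats_df <- rbind(
    if (nrow(up1)) data.frame(gene_id = up1$gene_id, class = levels(f)[1],
                              log2fc = -up1$log2fc, fdr = up1$fdr),
    if (nrow(up2)) data.frame(gene_id = up2$gene_id, class = levels(f)[2],
                              log2fc = up2$log2fc, fdr = up2$fdr))
  signature_set(sets, stats = stats_df, provenance = "top_lineage_panels")
}

#' Hypergeometric over-representation test
#'
#' One-sided upper-tail hypergeometric p-value per gene set against a fixed
#' universe, BH-adjusted across sets. Sets disjoint from the universe are
#' skipped with a warning.
#'
#' @param hits character vector of hit genes (must be within `universe`)
#' @param universe character vector of background genes
#' @param sets a [gene_set_collection] (or named list)
#' @return data.frame with `set`, `set_size` (within universe), `overlap`,
#'   `p`, `fdr`
#' @export
hypergeom_enrichment <- function(hits, universe, sets) {
  if (inherits(sets, "gene_set_collection")) sets <- sets$sets
  universe <- unique(universe)
  hits <- unique(hits)
  if (!all(hits %in% universe))
    stop("hit gene(s) outside the universe")
  rows <- list()
  for (nm in names(sets)) {
    s <- intersect(sets[[nm]], universe)
    if (!length(s)) {
      warning("set ", nm, " is disjoint from the universe; skipped")
      next
    }
    k <- length(intersect(hits, s))
    p <- stats::phyper(k - 1, m = length(s),
                       n = length(universe) - length(s),
                       k = length(hits), lower.tail = FALSE)
    rows[[nm]] <- data.frame(set = nm, set_size = length(s), overlap = k,
                             p = p)
  }
  out <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
         else data.frame(set = character(0), set_size = integer(0),
                         overlap = integer(0), p = numeric(0))
  out$fdr <- if (nrow(out)) bh_adjust(out$p) else numeric(0)
  out
}
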