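#' Specify a synthetic bulk or single-cell simulation
#'
#' Defines populations, planted lineage-specific genes, negative-binomial
#' noise, library-size variation, optional mean-dependent dropout, an
#' optional intermediate population whose gene means interpolate two parent
#' populations on the linear scale, and an optional rare mixed-lineage
#' subset of host cells whose randomly chosen donor-specific genes take the
#' donor population's means.
#'
#' Gene baseline means are drawn log-uniformly over `base_cpm_range`
#' (nominal CPM at the target library size). Planted specific genes take an
#' off-lineage baseline from `specific_off_cpm_range` when given (silent
#' marker-like genes), otherwise from `base_cpm_range`; the owning
#' population's mean is the baseline times `2^log2fc`.
#'
#' @param n_genes number of genes
#' @param groups named list: `name -> list(n_samples, lib_target)` where
#'   `lib_target` is the median library size in reads
#' @param signature_plan named list: `group -> list(n_specific_genes,
#'   log2fc)`; groups absent from the plan get no specific genes
#' @param phi_median median NB dispersion; per-gene dispersions are
#'   lognormal around it with sdlog `phi_sigma`
#' @param phi_sigma sdlog of the gene-wise dispersion distribution (0 =
#'   constant dispersion)
#' @param libsize_sigma sdlog of the lognormal library sizes
#' @param base_cpm_range log-uniform range of baseline gene means (CPM)
#' @param specific_off_cpm_range log-uniform range of the off-lineage
#'   baseline of planted specific genes, or `NULL` to use `base_cpm_range`
#' @param gene_length_range log-uniform range of gene lengths in bp
#' @param dropout `NULL` (off, the default) or
#'   `list(midpoint_log2cpm=, slope=)`: entries are zeroed with probability
#'   `plogis(slope * (midpoint_log2cpm - log2 CPM of the expected mean))`
#' @param intermediate_plan `NULL` or `list(name=, parent_a=, parent_b=,
#'   n_cells=, alpha=, mode=, outside_factor=)`; `alpha` in `[0,1]` or
#'   `"uniform"` for per-cell weights; `mode="interpolate"` gives means
#'   `alpha*mean_a + (1-alpha)*mean_b`, `mode="outside"` plants means at
#'   `outside_factor * pmax(mean_a, mean_b)` (an anti-monotone control)
#' @param mixed_plan `NULL` or `list(host=, donor=, fraction=,
#'   n_swapped_genes=)`
#' @param seed integer seed; the same seed gives bit-identical output
#' @return a `simulation_design` list
#' @export
simulation_design <- function(n_genes = 2000,
                              groups = list(),
                              signature_plan = list(),
                              phi_median = 0.1,
                              phi_sigma = 0,
                              libsize_sigma = 0.3,
                              base_cpm_range = c(1, 500),
                              specific_off_cpm_range = NULL,
                              gene_length_range = c(2000, 6000),
                              dropout = NULL,
                              intermediate_plan = NULL,
                              mixed_plan = NULL,
                              seed = 1L) {
  stopifnot(n_genes >= 1, length(groups) >= 1)
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be a named list")
  for (g in groups) {
    stopifnot(g$n_samples >= 1, g$lib_target > 0)
  }
  if (phi_median <= 0) stop("phi_median must be > 0")
  if (phi_sigma < 0 || libsize_sigma < 0) stop("sigmas must be >= 0")
  stopifnot(all(base_cpm_range > 0), diff(base_cpm_range) >= 0)
  if (!is.null(specific_off_cpm_range))
    stopifnot(all(specific_off_cpm_range > 0))
  unknown <- setdiff(names(signature_plan), names(groups))
  if (length(unknown))
    stop("signature_plan for unknown group(s): ",
         paste(unknown, collapse = ", "))
  n_spec <- sum(vapply(signature_plan, function(p) p$n_specific_genes, 0))
  if (n_spec > n_genes) stop("more specific genes than genes")
  if (!is.null(intermediate_plan)) {
    ip <- intermediate_plan
    if (!all(c(ip$parent_a, ip$parent_b) %in% names(groups)))
      stop("intermediate_plan parents must be simulated groups")
    if (is.null(ip$name)) intermediate_plan$name <- "LumInt"
    if (is.null(ip$mode)) intermediate_plan$mode <- "interpolate"
    if (is.null(ip$outside_factor)) intermediate_plan$outside_factor <- 2
    if (!identical(ip$alpha, "uniform")) {
      if (is.null(ip$alpha)) intermediate_plan$alpha <- 0.5
      else stopifnot(ip$alpha >= 0, ip$alpha <= 1)
    }
  }
  if (!is.null(mixed_plan)) {
    mp <- mixed_plan
    if (!all(c(mp$host, mp$donor) %in% names(groups)))
      stop("mixed_plan host/donor must be simulated groups")
    stopifnot(mp$fraction >= 0, mp$fraction <= 1, mp$n_swapped_genes >= 1)
    if (is.null(signature_plan[[mp$donor]]))
      stop("mixed_plan donor group has no planted specific genes")
  }
  structure(list(n_genes = n_genes, groups = groups,
                 signature_plan = signature_plan,
                 phi_median = phi_median, phi_sigma = phi_sigma,
                 libsize_sigma = libsize_sigma,
                 base_cpm_range = base_cpm_range,
                 specific_off_cpm_range = specific_off_cpm_range,
                 gene_length_range = gene_length_range,
                 dropout = dropout,
                 intermediate_plan = intermediate_plan,
                 mixed_plan = mixed_plan,
                 seed = as.integer(seed)),
            class = "simulation_design")
}

#' Default bulk design: three sorted populations with replicates
#'
#' Three cell types (basal, LP, ML) with 5 replicate libraries each at
#' bulk depth, 100 planted type-specific genes per type at fold change 8,
#' constant dispersion 0.05.
#'
#' @param seed integer seed
#' @param n_reps replicates per cell type
#' @param log2fc planted log2 fold change of specific genes
#' @param phi NB dispersion
#' @export
default_bulk_design <- function(seed = 1L, n_reps = 5, log2fc = 3,
                                phi = 0.05) {
  simulation_design(
    n_genes = 2000,
    groups = list(basal = list(n_samples = n_reps, lib_target = 2e7),
                  LP    = list(n_samples = n_reps, lib_target = 2e7),
                  ML    = list(n_samples = n_reps, lib_target = 2e7)),
    signature_plan = list(
      basal = list(n_specific_genes = 100, log2fc = log2fc),
      LP    = list(n_specific_genes = 100, log2fc = log2fc),
      ML    = list(n_specific_genes = 100, log2fc = log2fc)),
    phi_median = phi, phi_sigma = 0, libsize_sigma = 0.3,
    seed = seed)
}

#' Default single-cell design: lineage populations with an intermediate and
#' a rare mixed-lineage subset
#'
#' Basal, LP and ML populations of 200 deep cells each, 100 marker-like
#' specific genes per lineage (near-silent off-lineage, log2FC 8), a
#' luminal-intermediate population of 200 cells whose means sit halfway
#' between LP and ML on the linear scale, and 5% of basal cells carrying 12
#' randomly swapped LP-specific genes at donor level. Dispersion 0.1,
#' dropout off.
#'
#' @param seed integer seed
#' @param n_cells cells per population
#' @param with_intermediate include the LumInt population
#' @param with_mixed include the planted mixed-lineage basal cells
#' @export
default_cell_design <- function(seed = 1L, n_cells = 200,
                                with_intermediate = TRUE,
                                with_mixed = TRUE) {
  simulation_design(
    n_genes = 2000,
    groups = list(basal = list(n_samples = n_cells, lib_target = 1e6),
                  LP    = list(n_samples = n_cells, lib_target = 1e6),
                  ML    = list(n_samples = n_cells, lib_target = 1e6)),
    signature_plan = list(
      basal = list(n_specific_genes = 100, log2fc = 8),
      LP    = list(n_specific_genes = 100, log2fc = 8),
      ML    = list(n_specific_genes = 100, log2fc = 8)),
    phi_median = 0.1, phi_sigma = 0, libsize_sigma = 0.3,
    specific_off_cpm_range = c(0.05, 0.4),
    intermediate_plan = if (with_intermediate)
      list(name = "LumInt", parent_a = "LP", parent_b = "ML",
           n_cells = n_cells, alpha = 0.5, mode = "interpolate"),
    mixed_plan = if (with_mixed)
      list(host = "basal", donor = "LP", fraction = 0.05,
           n_swapped_genes = 12),
    seed = seed)
}

rlogunif <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else exp(stats::runif(n, log(range[1]), log(range[2])))
}

# Build the per-gene x per-group matrix of expected CPM plus the planted
# truth (specific gene sets per group).
plant_means <- function(design) {
  n <- design$n_genes
  gene_ids <- sprintf("g%04d", seq_len(n))
  base <- rlogunif(n, design$base_cpm_range)
  # rescale so baseline means are true CPM (sum to 1e6) and realized
  # library sizes land on the group's lib_target; off-lineage baselines of
  # specific genes (specific_off_cpm_range) are already on the CPM scale
  base <- base * 1e6 / sum(base)
  grp_names <- names(design$groups)
  mean_cpm <- matrix(base, n, length(grp_names),
                     dimnames = list(gene_ids, grp_names))
  specific <- list()
  pool <- seq_len(n)
  for (s in names(design$signature_plan)) {
    plan <- design$signature_plan[[s]]
    idx <- sort(pool[sample.int(length(pool), plan$n_specific_genes)])
    pool <- setdiff(pool, idx)
    if (!is.null(design$specific_off_cpm_range)) {
      off <- rlogunif(length(idx), design$specific_off_cpm_range)
      mean_cpm[idx, ] <- off
    }
    mean_cpm[idx, s] <- mean_cpm[idx, s] * 2^plan$log2fc
    specific[[s]] <- gene_ids[idx]
  }
  list(gene_ids = gene_ids, mean_cpm = mean_cpm, specific = specific)
}

nb_draw <- function(mu, phi) {
  # NB with var = mu + phi mu^2; phi -> 0 approaches Poisson
  k <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / phi),
              nrow(mu), ncol(mu))
  dimnames(k) <- dimnames(mu)
  k
}

simulate_core <- function(design, single_cell) {
  set.seed(design$seed)
  pl <- plant_means(design)
  n <- design$n_genes
  gene_lengths <- round(rlogunif(n, design$gene_length_range))
  phi <- design$phi_median * exp(stats::rnorm(n, 0, design$phi_sigma))

  pops <- names(design$groups)
  cell_ids <- character(0)
  labels <- character(0)
  mu_cols <- list()
  libsizes <- numeric(0)
  cpm_cols <- list()

  for (s in pops) {
    g <- design$groups[[s]]
    ids <- sprintf("%s_c%03d", s, seq_len(g$n_samples))
    ls <- exp(stats::rnorm(g$n_samples, log(g$lib_target),
                           design$libsize_sigma))
    cpm <- matrix(pl$mean_cpm[, s], n, g$n_samples,
                  dimnames = list(pl$gene_ids, ids))
    cell_ids <- c(cell_ids, ids)
    labels <- c(labels, rep(s, g$n_samples))
    libsizes <- c(libsizes, ls)
    cpm_cols[[s]] <- cpm
  }

  intermediate_alpha <- NULL
  ip <- design$intermediate_plan
  if (!is.null(ip) && single_cell) {
    ids <- sprintf("%s_c%03d", ip$name, seq_len(ip$n_cells))
    ls <- exp(stats::rnorm(ip$n_cells,
                           log(design$groups[[ip$parent_a]]$lib_target),
                           design$libsize_sigma))
    a <- if (identical(ip$alpha, "uniform")) stats::runif(ip$n_cells)
         else rep(ip$alpha, ip$n_cells)
    ma <- pl$mean_cpm[, ip$parent_a]
    mb <- pl$mean_cpm[, ip$parent_b]
    cpm <- if (identical(ip$mode, "outside")) {
      # plant the intermediate outside [parent_a, parent_b] only where the
      # parents actually differ; a uniform multiple of pmax would be
      # cancelled by library-size normalization downstream
      m_out <- ifelse(ma != mb, ip$outside_factor * pmax(ma, mb), ma)
      matrix(m_out, n, ip$n_cells)
    } else {
      outer(ma, a) + outer(mb, 1 - a)
    }
    dimnames(cpm) <- list(pl$gene_ids, ids)
    cell_ids <- c(cell_ids, ids)
    labels <- c(labels, rep(ip$name, ip$n_cells))
    libsizes <- c(libsizes, ls)
    cpm_cols[[ip$name]] <- cpm
    intermediate_alpha <- stats::setNames(a, ids)
  }

  cpm_all <- do.call(cbind, cpm_cols)
  cpm_all <- cpm_all[, cell_ids, drop = FALSE]

  mixed_cells <- character(0)
  swapped <- list()
  mp <- design$mixed_plan
  if (!is.null(mp) && single_cell) {
    host_idx <- which(labels == mp$host)
    n_mixed <- round(mp$fraction * length(host_idx))
    if (mp$fraction > 0 && n_mixed < 1)
      warning("mixed fraction too small for host population; 0 mixed cells")
    if (n_mixed >= 1) {
      pick <- sort(sample(host_idx, n_mixed))
      donor_genes <- pl$specific[[mp$donor]]
      for (ci in pick) {
        gsel <- sort(sample(donor_genes, mp$n_swapped_genes))
        cpm_all[gsel, ci] <- pl$mean_cpm[gsel, mp$donor]
        swapped[[cell_ids[ci]]] <- gsel
      }
      mixed_cells <- cell_ids[pick]
    }
  }

  mu <- sweep(cpm_all / 1e6, 2, libsizes, `*`)
  counts <- nb_draw(mu, phi)

  if (!is.null(design$dropout)) {
    dp <- design$dropout
    p_drop <- stats::plogis(dp$slope * (dp$midpoint_log2cpm -
                                        log2(pmax(cpm_all, 1e-8))))
    keep <- matrix(stats::runif(length(counts)) >= p_drop,
                   nrow(counts), ncol(counts))
    counts <- counts * keep
  }

  cm <- count_matrix(counts,
                     gene_ids = pl$gene_ids,
                     gene_lengths = gene_lengths,
                     sample_ids = cell_ids,
                     sample_meta = data.frame(
                       group = labels,
                       platform = if (single_cell) "synthetic_sc"
                                  else "synthetic_bulk"))
  truth <- structure(
    list(cell_labels = stats::setNames(labels, cell_ids),
         specific_genes = pl$specific,
         mixed_cells = mixed_cells,
         swapped_genes_per_cell = swapped,
         intermediate_alpha = intermediate_alpha,
         mean_cpm = pl$mean_cpm,
         phi = stats::setNames(phi, pl$gene_ids)),
    class = "sim_truth")
  list(counts = cm, truth = truth)
}

#' Simulate bulk replicate counts with planted type-specific genes
#'
#' Counts are NB with library-size-scaled group means and gene-wise
#' dispersion; group means differ by the planted log2FC exactly on specific
#' genes and are equal elsewhere.
#'
#' @param design a [simulation_design]; intermediate/mixed/dropout plans are
#'   ignored for bulk
#' @return list with `counts` (a [count_matrix]) and `truth` (planted
#'   labels, specific gene sets, expected means, dispersions)
#' @export
simulate_bulk <- function(design) {
  if (any(vapply(design$groups, function(g) g$n_samples, 0) < 2))
    stop("bulk simulation needs >= 2 replicates per group")
  simulate_core(design, single_cell = FALSE)
}

#' Simulate single-cell counts with lineage structure and known truth
#'
#' Generates the planted populations of `design` plus, when configured, an
#' intermediate population interpolating two parents on the linear mean
#' scale and a rare mixed-lineage subset of host cells with swapped
#' donor-specific genes. Optional dropout zeroes entries with probability
#' logistic in the log2-CPM of the expected mean.
#'
#' @param design a [simulation_design]
#' @return list with `counts` and `truth` as for [simulate_bulk()]
#' @export
simulate_cells <- function(design) {
  simulate_core(design, single_cell = TRUE)
}

#' @export
#' @method print sim_truth
print.sim_truth <- function(x, ...) {
  cat("sim_truth:", length(x$cell_labels), "samples,",
      length(x$specific_genes), "signature classes,",
      length(x$mixed_cells), "mixed cells\n")
  invisible(x)
}
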