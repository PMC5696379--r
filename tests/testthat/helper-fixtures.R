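# Shared fixtures and independent oracles, built in code.

toy_counts <- function(counts, lengths = NULL, groups = NULL, ...) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%02d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("c%02d", seq_len(ncol(counts)))
  count_matrix(counts,
               gene_lengths = lengths,
               sample_meta = if (!is.null(groups))
                 data.frame(group = groups),
               ...)
}

# NB counts at fixed dispersion for a one/two/three-group layout
sim_nb_groups <- function(n_genes, n_per_group, mu_by_group, phi,
                          libsize = NULL, seed = 1) {
  set.seed(seed)
  k <- length(mu_by_group)
  cols <- list()
  for (g in seq_len(k)) {
    mu <- matrix(mu_by_group[[g]], n_genes, n_per_group)
    cols[[g]] <- matrix(rnbinom(length(mu), mu = mu, size = 1 / phi),
                        n_genes, n_per_group)
  }
  m <- do.call(cbind, cols)
  rownames(m) <- sprintf("g%04d", seq_len(n_genes))
  colnames(m) <- sprintf("s%03d", seq_len(ncol(m)))
  groups <- rep(paste0("grp", seq_len(k)), each = n_per_group)
  toy_counts(m, groups = groups)
}

# Brute-force step-up BH oracle
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Exhaustive hypergeometric upper-tail oracle by enumeration over all
# subsets of the universe of size |hits| (N <= 12)
hyper_oracle <- function(k_obs, set, universe, n_hits) {
  combs <- utils::combn(length(universe), n_hits)
  inset <- universe %in% set
  overlaps <- apply(combs, 2, function(ix) sum(inset[ix]))
  mean(overlaps >= k_obs)
}

# Brute-force leading-logFC RMS oracle
leading_rms_oracle <- function(x, k) {
  n <- ncol(x)
  d <- matrix(0, n, n)
  kk <- min(k, nrow(x))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    dd <- sort(abs(x[, i] - x[, j]), decreasing = TRUE)[seq_len(kk)]
    d[i, j] <- sqrt(mean(dd^2))
  }
  d
}

# Grid-search ML oracle for the NB one-group mean (offsets included)
nb_mean_ll_oracle <- function(y, offs, phi, beta_grid) {
  ll <- vapply(beta_grid, function(b)
    sum(dnbinom(y, mu = exp(b + offs), size = 1 / phi, log = TRUE)), 0)
  list(beta = beta_grid[which.max(ll)], ll = max(ll))
}
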