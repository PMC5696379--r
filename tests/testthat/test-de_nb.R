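test_that("the NB mean fit matches a grid-search likelihood oracle", {
  set.seed(50)
  y <- matrix(rnbinom(5 * 8, mu = c(2, 10, 50, 200, 800), size = 10),
              5, 8)
  offs <- log(runif(8, 0.5e6, 2e6))
  y2 <- matrix(rnbinom(length(y), mu = sweep(matrix(c(2, 10, 50, 200, 800),
                                                    5, 8), 2,
                                             exp(offs) / 1e6, `*`),
                       size = 10), 5, 8)
  fit <- mamlin:::fit_nb_mean(y2, offs, rep(0.1, 5))
  for (g in 1:5) {
    grid <- seq(fit$beta[g] - 0.5, fit$beta[g] + 0.5, length.out = 2001)
    oracle <- nb_mean_ll_oracle(y2[g, ], offs, 0.1, grid)
    expect_lt(abs(fit$beta[g] - oracle$beta), 1e-3)
    expect_gte(fit$ll[g], oracle$ll - 1e-6)
  }
})

test_that("LRT detects planted effects and rejects single-group input", {
  cm <- sim_nb_groups(50, 20,
                      list(rep(100, 50), c(rep(1600, 10), rep(100, 40))),
                      phi = 0.1, seed = 51)
  de <- lrt_de(cm, disp = 0.1,
               lib_sizes = rep(sum(cm$counts[, 1]), 40))
  expect_true(all(de$p[1:10] < 1e-6))  # planted log2FC = 4
  expect_error(lrt_de(cm, rep("A", 40), disp = 0.1), ">= 2 groups")
})

test_that("LRT is invariant to permuting samples within groups", {
  cm <- sim_nb_groups(30, 6, list(rep(50, 30), rep(50, 30)), 0.1,
                      seed = 52)
  g <- sample_groups(cm)
  de1 <- lrt_de(cm, g, disp = 0.1)
  perm <- c(sample(1:6), sample(7:12))
  de2 <- lrt_de(cm[, perm], g[perm], disp = 0.1)
  expect_equal(de2$p, de1$p, tolerance = 1e-10)
})

test_that("multi-group LRT handles a one-way three-group layout", {
  cm <- sim_nb_groups(40, 8,
                      list(rep(100, 40),
                           c(rep(400, 5), rep(100, 35)),
                           c(rep(25, 5), rep(100, 35))),
                      phi = 0.05, seed = 53)
  de <- lrt_de(cm, disp = 0.05, lib_sizes = rep(1e6, 24))
  expect_equal(de$contrast[1], "grp1/grp2/grp3")
  expect_true(all(de$p[1:5] < 1e-4))
  expect_gt(min(de$p[6:40]), 1e-4)
})

test_that("the threshold test reduces to the LRT at tau 1 and is never
           more liberal above it", {
  cm <- sim_nb_groups(200, 8,
                      list(rep(80, 200),
                           c(rep(320, 40), rep(80, 160))),
                      phi = 0.1, seed = 54)
  de <- lrt_de(cm, disp = 0.1)
  tr1 <- treat_test(cm, disp = 0.1, tau = 1)
  expect_equal(tr1$p, de$p, tolerance = 1e-8)
  for (tau in c(1.3, 2, 3)) {
    tr <- treat_test(cm, disp = 0.1, tau = tau)
    expect_true(all(tr$p >= de$p - 1e-12))
  }
  expect_error(treat_test(cm, disp = 0.1, tau = 0.5), "tau")
})

test_that("dispersion estimation recovers the truth and its limits", {
  cm <- sim_nb_groups(200, 10, list(exp(runif(200, log(10), log(500))),
                                    exp(runif(200, log(10), log(500)))),
                      phi = 0.1, seed = 55)
  dm <- estimate_dispersions(cm)
  expect_gt(dm$common_phi, 0.05)
  expect_lt(dm$common_phi, 0.2)

  # agreement with the reference estimator
  g <- sample_groups(cm)
  dge <- edgeR::DGEList(counts = cm$counts, group = g)
  dge <- edgeR::estimateDisp(dge, model.matrix(~g))
  expect_equal(dm$common_phi, dge$common.dispersion, tolerance = 0.05)

  # Poisson data push the estimate to the grid floor
  set.seed(56)
  mp <- matrix(rpois(200 * 20, 100), 200, 20)
  rownames(mp) <- sprintf("g%03d", 1:200)
  colnames(mp) <- sprintf("s%02d", 1:20)
  dp <- estimate_dispersions(count_matrix(mp), rep(c("A", "B"), each = 10))
  expect_lte(dp$common_phi, 0.01)

  # infinite shrinkage collapses tagwise onto common
  dInf <- estimate_dispersions(cm, shrink_weight = Inf)
  expect_true(all(dInf$tagwise_phi == dInf$common_phi))
  expect_error(estimate_dispersions(
    count_matrix(matrix(0, 2, 2,
                        dimnames = list(c("a", "b"), c("x", "y"))))),
    "all-zero")
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_warning(out <- bh_adjust(c(0.1, NaN, 0.5)), "NaN")
  expect_true(is.na(out[2]))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(57)
  for (n in c(1, 2, 10, 137, 1000)) {
    p <- runif(n)^2
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
    expect_equal(bh_adjust(p), p.adjust(p, "BH"))
    expect_true(all(bh_adjust(p) >= p))
  }
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  set.seed(58)
  for (rep in 1:20) {
    n_univ <- sample(5:12, 1)
    universe <- sprintf("u%02d", seq_len(n_univ))
    set_g <- sample(universe, sample(1:n_univ, 1))
    hits <- sample(universe, sample(1:4, 1))
    res <- hypergeom_enrichment(hits, universe,
                                list(s = set_g))
    k <- length(intersect(hits, set_g))
    expect_equal(res$overlap, k)
    expect_equal(res$p, hyper_oracle(k, set_g, universe, length(hits)),
                 tolerance = 1e-12)
  }
  # set identical to hits in a small universe: minimal possible p
  universe <- letters[1:8]
  res <- hypergeom_enrichment(letters[1:3], universe,
                              list(s = letters[1:3]))
  expect_equal(res$p, 1 / choose(8, 3), tolerance = 1e-12)
  # empty overlap with a large set is uninteresting
  res2 <- hypergeom_enrichment("a", universe, list(s = letters[4:8]))
  expect_gt(res2$p, 0.6)
  expect_warning(
    res3 <- hypergeom_enrichment("a", universe, list(s = c("zz"))),
    "disjoint")
  expect_equal(nrow(res3), 0L)
  expect_error(hypergeom_enrichment(c("a", "zz"), universe,
                                    list(s = letters[1:3])), "universe")
})

test_that("signature derivation requires upregulation against both rivals", {
  # gene 1 up in basal vs LP only; gene 2 up in basal vs both
  mu_basal <- c(800, 800, rep(100, 28))
  mu_lp <- c(100, 100, rep(100, 28))
  mu_ml <- c(800, 100, rep(100, 28))
  cm <- sim_nb_groups(30, 6, list(mu_basal, mu_lp, mu_ml), 0.02,
                      seed = 59)
  g <- c("basal", "LP", "ML")[rep(1:3, each = 6)]
  cm$sample_meta <- data.frame(group = g, row.names = cm$sample_ids)
  sigs <- derive_signatures(cm, disp = 0.02)
  expect_false("g0001" %in% sigs$sets$basal)
  expect_true("g0002" %in% sigs$sets$basal)

  expect_error(derive_signatures(cm, tau_map = c(LP_vs_basal = 2),
                                 disp = 0.02), "threshold for contrast")

  # null data: no genes pass, no error
  null_cm <- sim_nb_groups(40, 4, list(rep(50, 40), rep(50, 40),
                                       rep(50, 40)), 0.05, seed = 60)
  gn <- c("basal", "LP", "ML")[rep(1:3, each = 4)]
  sn <- derive_signatures(null_cm, gn, disp = 0.05)
  expect_lte(length(unlist(sn$sets)), 2L)
})

test_that("biotype filtering restricts signature derivation", {
  cm <- sim_nb_groups(30, 4,
                      list(c(rep(1000, 4), rep(100, 26)),
                           rep(100, 30), rep(100, 30)),
                      0.02, seed = 61)
  g <- c("basal", "LP", "ML")[rep(1:3, each = 4)]
  bio <- rep("protein_coding", 30)
  bio[1:2] <- "lincRNA"
  sigs <- derive_signatures(cm, g, disp = 0.02, biotype = bio)
  expect_false(any(c("g0001", "g0002") %in% unlist(sigs$sets)))
  expect_true(all(c("g0003", "g0004") %in% sigs$sets$basal))
})

test_that("top lineage panels rank, truncate and flip with group labels", {
  # balanced planting: 300 up-genes per side so library compositions match
  n <- 2000
  mu_b <- rep(100, n); mu_l <- rep(100, n)
  mu_b[1:300] <- 800       # basal-up
  mu_l[301:600] <- 800     # luminal-up
  cm <- sim_nb_groups(n, 8, list(mu_b, mu_l), 0.05, seed = 62)
  g <- rep(c("basal", "luminal"), each = 8)
  cm$sample_meta <- data.frame(group = g, row.names = cm$sample_ids)
  panels <- top_lineage_panels(cm, tau = 3, n_top = 200, disp = 0.05)
  expect_length(panels$sets$basal, 200L)
  expect_length(panels$sets$luminal, 200L)
  expect_true(all(panels$sets$basal %in% sprintf("g%04d", 1:300)))
  expect_true(all(panels$sets$luminal %in% sprintf("g%04d", 301:600)))

  # relabelling the groups swaps the two panels
  gf <- rep(c("luminal", "basal"), each = 8)
  flipped <- top_lineage_panels(cm, gf, tau = 3, n_top = 200,
                                disp = 0.05)
  expect_setequal(flipped$sets$basal, panels$sets$luminal)
  expect_setequal(flipped$sets$luminal, panels$sets$basal)

  # asking for more than is significant warns and returns all
  # both panel sides fall short of 500, so two warnings fire
  expect_warning(
    expect_warning(big <- top_lineage_panels(cm, g, tau = 3, n_top = 500,
                                             disp = 0.05),
                   "significant genes"),
    "significant genes")
  expect_lt(length(big$sets$basal), 500L)
  expect_gte(length(big$sets$basal), 250L)

  empty <- top_lineage_panels(cm, g, tau = 3, n_top = 0, disp = 0.05)
  expect_length(empty$sets$basal, 0L)
})
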