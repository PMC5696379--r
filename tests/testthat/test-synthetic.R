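test_that("identical seeds give bit-identical simulations", {
  a <- simulate_cells(default_cell_design(seed = 9))
  b <- simulate_cells(default_cell_design(seed = 9))
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth$mixed_cells, b$truth$mixed_cells)
  c <- simulate_cells(default_cell_design(seed = 10))
  expect_false(identical(a$counts$counts, c$counts$counts))
})

test_that("generated counts match NB moments and the Poisson limit", {
  base <- list(n_samples = 400, lib_target = 1e6)
  des <- simulation_design(n_genes = 60, groups = list(A = base),
                           phi_median = 0.2, libsize_sigma = 0,
                           seed = 2)
  sim <- simulate_cells(des)
  mu <- sim$truth$mean_cpm[, "A"]  # libsize fixed at 1e6 => mu = cpm
  emp_mean <- rowMeans(sim$counts$counts)
  emp_var <- apply(sim$counts$counts, 1, var)
  # mean within 4 SE of mu; variance ratio to mu + phi mu^2 near 1
  se <- sqrt((mu + 0.2 * mu^2) / 400)
  expect_true(all(abs(emp_mean - mu) < 4 * se + 1e-9))
  big <- mu > 20
  expect_lt(median(abs(emp_var[big] / (mu + 0.2 * mu^2)[big] - 1)), 0.25)

  # phi -> 0: variance tracks the mean
  desp <- simulation_design(n_genes = 60, groups = list(A = base),
                            phi_median = 1e-8, libsize_sigma = 0,
                            seed = 3)
  simp <- simulate_cells(desp)
  mup <- simp$truth$mean_cpm[, "A"]
  varp <- apply(simp$counts$counts, 1, var)
  bigp <- mup > 20
  expect_lt(median(abs(varp[bigp] / mup[bigp] - 1)), 0.25)
})

test_that("null designs share group means; planted log2FC is recovered", {
  groups <- list(A = list(n_samples = 50, lib_target = 1e6),
                 B = list(n_samples = 50, lib_target = 1e6))
  null_des <- simulation_design(n_genes = 100, groups = groups,
                                libsize_sigma = 0, seed = 4)
  sim <- simulate_cells(null_des)
  g <- sample_groups(sim$counts)
  ra <- rowMeans(sim$counts$counts[, g == "A"])
  rb <- rowMeans(sim$counts$counts[, g == "B"])
  mu <- sim$truth$mean_cpm[, "A"]
  se <- sqrt(2 * (mu + 0.1 * mu^2) / 50)
  expect_true(mean(abs(ra - rb) < 3 * se) > 0.95)

  fc_des <- simulation_design(
    n_genes = 100, groups = groups,
    signature_plan = list(B = list(n_specific_genes = 30, log2fc = 3)),
    libsize_sigma = 0, seed = 5)
  simf <- simulate_cells(fc_des)
  gf <- sample_groups(simf$counts)
  spec <- simf$truth$specific_genes$B
  ratio <- rowMeans(simf$counts$counts[spec, gf == "B"]) /
    rowMeans(simf$counts$counts[spec, gf == "A"])
  expect_true(all(abs(log2(ratio) - 3) < 1))
  expect_lt(abs(mean(log2(ratio)) - 3), 0.15)
})

test_that("alpha = 1 intermediates are distributed like parent_a", {
  des <- simulation_design(
    n_genes = 200,
    groups = list(LP = list(n_samples = 200, lib_target = 1e6),
                  ML = list(n_samples = 200, lib_target = 1e6)),
    signature_plan = list(LP = list(n_specific_genes = 30, log2fc = 4),
                          ML = list(n_specific_genes = 30, log2fc = 4)),
    intermediate_plan = list(name = "Int", parent_a = "LP",
                             parent_b = "ML", n_cells = 200, alpha = 1),
    libsize_sigma = 0, seed = 6)
  sim <- simulate_cells(des)
  g <- sample_groups(sim$counts)
  m_lp <- rowMeans(sim$counts$counts[, g == "LP"])
  m_int <- rowMeans(sim$counts$counts[, g == "Int"])
  expressed <- m_lp > 5
  expect_lt(median(abs(log2((m_int[expressed] + 0.5) /
                            (m_lp[expressed] + 0.5)))), 0.1)
  expect_equal(unname(sim$truth$intermediate_alpha),
               rep(1, 200))
})

test_that("zero fractions match the closed-form NB zero mass", {
  des <- simulation_design(n_genes = 40,
                           groups = list(A = list(n_samples = 500,
                                                  lib_target = 1e6)),
                           phi_median = 0.5, libsize_sigma = 0, seed = 7)
  sim <- simulate_cells(des)
  mu <- sim$truth$mean_cpm[, "A"]
  p0_theory <- (1 + 0.5 * mu)^(-1 / 0.5)
  p0_emp <- rowMeans(sim$counts$counts == 0)
  se <- sqrt(p0_theory * (1 - p0_theory) / 500)
  expect_true(all(abs(p0_emp - p0_theory) < 4 * se + 0.01))
})

test_that("dropout thins low-expression genes preferentially", {
  groups <- list(A = list(n_samples = 300, lib_target = 1e6))
  # baseline means are rescaled to true CPM (summing to 1e6), so with
  # 100 genes the realized range sits around 2^11-2^12; centre the
  # dropout curve there
  des <- simulation_design(n_genes = 100, groups = groups,
                           libsize_sigma = 0, seed = 8,
                           dropout = list(midpoint_log2cpm = 11.5,
                                          slope = 1))
  base <- simulation_design(n_genes = 100, groups = groups,
                            libsize_sigma = 0, seed = 8)
  with_do <- simulate_cells(des)
  without <- simulate_cells(base)
  mu <- with_do$truth$mean_cpm[, "A"]
  low <- mu < 2^10.5; high <- mu > 2^12.5
  extra_low <- mean(with_do$counts$counts[low, ] == 0) -
    mean(without$counts$counts[low, ] == 0)
  extra_high <- mean(with_do$counts$counts[high, ] == 0) -
    mean(without$counts$counts[high, ] == 0)
  expect_gt(extra_low, 0.2)
  expect_lt(extra_high, 0.1)
})

test_that("mixed-cell bookkeeping is exact", {
  des <- default_cell_design(seed = 11, with_intermediate = FALSE)
  sim <- simulate_cells(des)
  expect_length(sim$truth$mixed_cells, 10L)  # 5% of 200 basal cells
  expect_true(all(sim$truth$cell_labels[sim$truth$mixed_cells] == "basal"))
  swapped <- sim$truth$swapped_genes_per_cell
  expect_equal(sort(names(swapped)), sort(sim$truth$mixed_cells))
  expect_true(all(lengths(swapped) == 12L))
  expect_true(all(unlist(swapped) %in% sim$truth$specific_genes$LP))

  tiny <- default_cell_design(seed = 12, n_cells = 5,
                              with_intermediate = FALSE)
  tiny$mixed_plan$fraction <- 0.01
  expect_warning(sim2 <- simulate_cells(tiny), "0 mixed cells")
  expect_length(sim2$truth$mixed_cells, 0L)
})

test_that("design validation catches inconsistent plans", {
  groups <- list(A = list(n_samples = 4, lib_target = 1e6))
  expect_error(simulation_design(groups = list()), "length")
  expect_error(simulation_design(
    n_genes = 10, groups = groups,
    signature_plan = list(B = list(n_specific_genes = 2, log2fc = 1))),
    "unknown group")
  expect_error(simulation_design(
    n_genes = 10, groups = groups,
    signature_plan = list(A = list(n_specific_genes = 20, log2fc = 1))),
    "more specific genes")
  expect_error(simulation_design(
    n_genes = 10, groups = groups,
    intermediate_plan = list(parent_a = "A", parent_b = "Z",
                             n_cells = 3)),
    "parents")
  expect_error(simulate_bulk(simulation_design(
    n_genes = 10, groups = list(A = list(n_samples = 1,
                                         lib_target = 1e6)))),
    "2 replicates")
})
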