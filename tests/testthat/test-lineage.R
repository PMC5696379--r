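make_expr <- function(m, normalization = "quantile_log2cpm") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("c%02d", seq_len(ncol(m)))
  expr_matrix(m, normalization)
}

three_sets <- list(basal = c("g01", "g02"), LP = c("g03", "g04"),
                   ML = c("g05", "g06"))

test_that("ternary scores place pure and degenerate cells correctly", {
  # cell1 expresses only basal genes above floor 0; cell2 nothing
  m <- rbind(c(4, 0), c(2, 0), c(0, 0), c(0, 0), c(0, 0), c(0, 0))
  sc <- ternary_cell_scores(make_expr(m), three_sets, floor = 0)
  expect_equal(unname(unlist(sc[1, c("basal", "LP", "ML")])), c(1, 0, 0))
  expect_equal(sc$label[1], "basal")
  expect_false(sc$degenerate[1])
  expect_equal(unname(unlist(sc[2, c("basal", "LP", "ML")])),
               rep(1 / 3, 3))
  expect_true(sc$degenerate[2])
})

test_that("ternary scores match hand arithmetic on a 2-gene-per-set toy", {
  m <- cbind(c(3, 1, 2, 0, 1, 1))  # floor 0
  sc <- ternary_cell_scores(make_expr(m), three_sets, floor = 0)
  # raw: basal (3+1)/2 = 2, LP (2+0)/2 = 1, ML (1+1)/2 = 1; total 4
  expect_equal(unname(unlist(sc[1, c("basal", "LP", "ML")])),
               c(0.5, 0.25, 0.25))
  expect_equal(sc$raw.basal, 2)
  # values below the floor are clipped, not subtracted
  sc2 <- ternary_cell_scores(make_expr(m), three_sets, floor = 1)
  expect_equal(sc2$raw.basal, (2 + 0) / 2)  # (3-1)/2, (1-1)/2
  expect_equal(sc2$raw.LP, 0.5)

  expect_error(ternary_cell_scores(make_expr(m),
                                   list(a = "g01", b = "g02",
                                        c = "nope")), "'c'")
})

test_that("the count scoring mode counts genes above the floor", {
  m <- cbind(c(3, 1, 2, 0, 0, 0))
  sc <- ternary_cell_scores(make_expr(m), three_sets, floor = 0,
                            method = "count")
  expect_equal(sc$raw.basal, 1)    # both basal genes detected
  expect_equal(sc$raw.LP, 0.5)     # one of two
  expect_equal(sc$raw.ML, 0)
})

test_that("ternary proportions are invariant to gene order and cell
           duplication", {
  set.seed(70)
  m <- matrix(runif(6 * 10, 0, 4), 6, 10)
  rownames(m) <- sprintf("g%02d", 1:6)
  colnames(m) <- sprintf("c%02d", 1:10)
  sc <- ternary_cell_scores(make_expr(m), three_sets, floor = 1)
  perm <- sample(6)
  sc2 <- ternary_cell_scores(make_expr(m[perm, ]), three_sets, floor = 1)
  expect_equal(sc2[c("basal", "LP", "ML")], sc[c("basal", "LP", "ML")])
  dup <- cbind(m, m)
  colnames(dup) <- sprintf("c%02d", 1:20)
  sc3 <- ternary_cell_scores(make_expr(dup), three_sets, floor = 1)
  expect_equal(unname(as.matrix(sc3[1:10, c("basal", "LP", "ML")])),
               unname(as.matrix(sc[c("basal", "LP", "ML")])))
  expect_equal(rowSums(as.matrix(sc[c("basal", "LP", "ML")])),
               rep(1, 10), tolerance = 1e-9)
})

test_that("cell classification applies argmax, band and tie rules", {
  sc <- data.frame(sample_id = c("a", "b", "c", "d"),
                   basal = c(0.1, 0.1, 1 / 3, 0.4),
                   LP = c(0.8, 0.46, 1 / 3, 0.4),
                   ML = c(0.1, 0.44, 1 / 3, 0.2),
                   degenerate = c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(classify_cells(sc),
               c("LP", "LP", "unclassified", "basal"))
  # banded Lum Int rule: |LP - ML| < b and both above basal
  expect_equal(classify_cells(sc, intermediate_band = 0.05),
               c("LP", "Lum Int", "unclassified", "basal"))
  # exact tie without a band: first class in fixed order wins
  expect_equal(classify_cells(sc)[4], "basal")
})

test_that("per-gene stage composition averages on the linear scale", {
  m <- rbind(g1 = c(8, 8, 0, 0, 0, 0),   # only stage A
             g2 = c(4, 4, 4, 4, 4, 4),   # equal everywhere
             g3 = c(2, 2, 4, 4, 8, 8))
  colnames(m) <- sprintf("c%d", 1:6)
  stages <- rep(c("A", "B", "C"), each = 2)
  # cpm input: means used directly
  comp <- ternary_gene_composition(expr_matrix(m, "cpm"), stages)
  expect_equal(unname(unlist(comp[1, c("A", "B", "C")])), c(1, 0, 0))
  expect_equal(unname(unlist(comp[2, c("A", "B", "C")])), rep(1 / 3, 3))
  expect_equal(unname(unlist(comp[3, c("A", "B", "C")])),
               c(2, 4, 8) / 14)
  # log2 input is exponentiated first
  compl <- ternary_gene_composition(expr_matrix(log2(m + 1), "log2cpm"),
                                    stages)
  expect_equal(unname(unlist(compl[2, c("A", "B", "C")])), rep(1 / 3, 3))
  expect_error(ternary_gene_composition(expr_matrix(m, "cpm"),
                                        rep(c("A", "B"), 3)), "3 stages")
})

test_that("mixed-lineage detection applies count and dominance rules", {
  sets <- list(basal = c("g01", "g02", "g03"), luminal = c("g04", "g05",
                                                           "g06"))
  # cell1: host only; cell2: host + 2 foreign; cell3: host + 3 foreign
  m <- cbind(c(8, 8, 8, 0, 0, 0),
             c(8, 8, 8, 5, 5, 0),
             c(8, 8, 8, 5, 5, 5))
  calls <- detect_mixed_lineage(make_expr(m, "log2rpkm"), "basal", sets,
                                min_foreign_genes = 3,
                                detect_log2rpkm = log2(5), floor = 0)
  expect_equal(calls$n_foreign_detected, c(0, 2, 3))
  expect_equal(calls$is_mixed, c(FALSE, FALSE, TRUE))
  expect_equal(calls$foreign_genes[3], "g04,g05,g06")

  # min_foreign_genes = 1: any detected foreign gene flags the cell
  calls1 <- detect_mixed_lineage(make_expr(m, "log2rpkm"), "basal", sets,
                                 min_foreign_genes = 1,
                                 detect_log2rpkm = log2(5), floor = 0)
  expect_equal(calls1$is_mixed, c(FALSE, TRUE, TRUE))

  # dominance: a luminal-dominated cell is not "mixed host"
  m2 <- cbind(c(1, 1, 1, 9, 9, 9))
  c2 <- detect_mixed_lineage(make_expr(m2, "log2rpkm"), "basal", sets,
                             min_foreign_genes = 3,
                             detect_log2rpkm = log2(5), floor = 0)
  expect_false(c2$is_mixed)

  expect_error(detect_mixed_lineage(make_expr(m), "basal",
                                    list(basal = c("g01"))), "differ")
})

test_that("marker flagging compares on the linear scale with strict >", {
  # log input is exponentiated before comparison (exact powers of two
  # avoid knife-edge float drift away from the boundary case)
  m <- rbind(Cd55 = log2(c(64, 39, 0.5)))
  colnames(m) <- sprintf("c%d", 1:3)
  ex <- expr_matrix(m, "log2rpkm")
  expect_equal(unname(flag_marker_positive(ex, "Cd55", 40)),
               c(TRUE, FALSE, FALSE))
  expect_equal(unname(flag_marker_positive(ex, "Cd55", 0)),
               rep(TRUE, 3))
  expect_error(flag_marker_positive(ex, "Krt5", 40), "absent")

  # the boundary is strict: exactly 40 is not flagged (linear input,
  # where the comparison is exact)
  lin <- expr_matrix(matrix(c(41, 40), 1, 2,
                            dimnames = list("Cd55", c("a", "b"))), "cpm")
  expect_equal(unname(flag_marker_positive(lin, "Cd55", 40)),
               c(TRUE, FALSE))
})
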