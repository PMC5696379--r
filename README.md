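# mamlin

Lineage-heterogeneity analysis of mammary epithelial RNA-seq counts.

The post-natal mouse mammary epithelium contains two primary lineages —
basal/myoepithelial cells and a luminal compartment split into
clonogenic luminal progenitors (LP) and hormone-sensing mature luminal
(ML) cells — plus rarer states of interest: a luminal-intermediate
transit population sitting between LP and ML, and scarce mixed-lineage
("lineage-primed") basal cells that co-express luminal genes. mamlin is
an R package for workers analysing single-cell and bulk RNA-seq of such
sorted populations: it takes gene-by-cell count matrices and carries
them through quality control, normalization, differential expression,
lineage-signature scoring, and structure/trend statistics, with a
synthetic count generator with planted ground truth used to validate
every stage.

## What it computes

* **QC** — remove mitochondrial/ribosomal/unannotated genes; drop cells
  with fewer than 100,000 assigned read pairs or fewer than 1,500
  detected genes (relaxed pair 50,000/1,000); drop genes failing 1 CPM
  in at least 3 cells; a housekeeping (ACTB/GAPDH) Ct filter for
  multiplex qPCR panels.
* **Normalization** — CPM; log2-CPM with prior count; log2-RPKM with a
  library-size-scaled prior count of 5; quantile normalization;
  per-gene standardization.
* **Differential expression** — self-contained negative-binomial GLMs
  (log link, library-size offsets): likelihood-ratio tests for two or
  more groups, Cox–Reid adjusted-profile-likelihood dispersion
  estimation with tagwise shrinkage, and a fold-change-threshold
  (TREAT-style) test of `H0: |log2FC| <= log2(tau)`. Signature
  derivation calls a gene cell-type specific when it is up against both
  other types (tau = 2 for basal vs LP/ML, 1.3 for LP vs ML, BH
  FDR < 0.05); two-class top-200 lineage panels use tau = 3. BH
  adjustment and hypergeometric over-representation round this out.
* **Lineage scoring** — per-cell ternary composition over three
  signature sets on quantile-normalized log2-CPM (proportions of
  expression above a floor), argmax classification with an optional
  luminal-intermediate band; per-gene stage composition; mixed-lineage
  detection (≥ 3 foreign-signature genes above RPKM 5 in a cell that
  stays host-dominant); marker flagging (e.g. CD55 at RPKM > 40).
* **Structure** — pairwise leading log-fold-change distances (RMS of
  the 500 largest per-gene log2 differences, per pair, compiled
  kernel), classical MDS with a fixed sign convention, Euclidean
  hierarchical clustering of standardized genes or cells.
* **Trends** — the monotone-trend statistic (fraction of DE genes whose
  intermediate-population mean lies between the LP and ML means), the
  "at least 20% higher" elevated-intermediate gene rule, and cell-cycle
  cluster flagging.
* **Networks** — map DE genes (FDR < 0.001) to human orthologs, induce
  the direct-interaction subnetwork, classify nodes as signal
  transduction / transcription factor / dual, export TSV + SIF.
* **Synthetic data** — `simulation_design()` / `simulate_bulk()` /
  `simulate_cells()` generate NB counts with gene-wise dispersion,
  lognormal library sizes, planted type-specific genes, an interpolated
  intermediate population, a rare mixed-lineage subset, optional
  dropout — and full ground truth for recovery testing.

## Worked example: recovering lineage-primed basal cells

```r
library(mamlin)

# simulate basal cells with a planted 5% lineage-primed subset
design <- default_cell_design(seed = 1, with_intermediate = FALSE)
sim <- simulate_cells(design)
sim$counts
#> count_matrix: 2000 genes x 600 samples
#>   gene lengths: present
#>   sample_meta columns: group, platform

basal <- names(sim$truth$cell_labels)[sim$truth$cell_labels == "basal"]
rpkm <- to_log2rpkm(sim$counts[, basal], prior = 5)
sigs <- signature_set(sim$truth$specific_genes)
sigs
#> signature_set with 3 classes:
#>   basal: 100 genes
#>   LP: 100 genes
#>   ML: 100 genes

calls <- detect_mixed_lineage(rpkm, host_class = "basal", sigs)
table(called = calls$is_mixed,
      planted = calls$sample_id %in% sim$truth$mixed_cells)
#>        planted
#> called  FALSE TRUE
#>   FALSE   190    0
#>   TRUE      0   10
```

All 10 planted mixed-lineage cells (5% of 200 basal cells, each with 12
LP-specific genes swapped to LP expression level) are recovered with no
false positives. The per-cell output lists the detected foreign genes
for audit:

```r
head(calls[calls$is_mixed, c("sample_id", "n_foreign_detected")], 3)
#>     sample_id n_foreign_detected
#> 8  basal_c008                 10
#> 19 basal_c019                 12
#> 20 basal_c020                 11
```

The four end-to-end workflows (`luminal`, `stages`, `basal`, `network`)
are run with `run_pipeline(default_config(), "luminal", out_dir = ...)`
or through the thin CLI at `inst/cli/mamlin`
(`mamlin run --workflow luminal --out out/ --seed 1`); outputs are TSV
files that are byte-identical across runs at a fixed seed.

## Documentation

The methods vignette (`vignettes/lineage-methods.Rmd`) describes the
models, every tunable threshold with its default and rationale, the
synthetic generator's assumptions and their limits, and the numerical
choices (tie-breaks, priors, grids, sign conventions).
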