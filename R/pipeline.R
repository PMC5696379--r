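#' Default pipeline configuration
#'
#' One block per stage; every tunable threshold of the pipeline appears
#' here with its default. [read_config()] merges a user YAML/JSON file
#' over these values and rejects unknown keys.
#'
#' @export
default_config <- function() {
  list(
    seed = 1L,
    synthetic = list(
      cells = list(n_cells = 200L),
      bulk = list(n_reps = 5L, log2fc = 3, phi = 0.05)),
    qc = list(min_read_pairs = 100000, min_detected_genes = 1500,
              relaxed_min_read_pairs = 50000,
              relaxed_min_detected_genes = 1000,
              min_cpm = 1, min_cells_at_cpm = 3, relaxed = FALSE),
    normalize = list(log2cpm_prior = 0.5, rpkm_prior = 5,
                     scale_prior = TRUE),
    de = list(fdr_cut = 0.05, tau_pairwise = 3, network_fdr = 0.001,
              shrink_weight = 10),
    lineage = list(intermediate_band = NULL,
                   min_foreign_genes = 3, detect_rpkm = 5,
                   host_dominance = 1, marker_threshold = 40),
    structure = list(k_top = 500L, dims = 2L, linkage = "complete"),
    trend = list(fdr_cut = 0.01, eps = 0, ratio = 1.2, z_margin = 0.5),
    network = list(edges = NULL, orthologs = NULL, functions = NULL))
}

qc_from_config <- function(cfg) {
  qc_thresholds(min_read_pairs = cfg$qc$min_read_pairs,
                min_detected_genes = cfg$qc$min_detected_genes,
                relaxed_min_read_pairs = cfg$qc$relaxed_min_read_pairs,
                relaxed_min_detected_genes = cfg$qc$relaxed_min_detected_genes,
                min_cpm = cfg$qc$min_cpm,
                min_cells_at_cpm = cfg$qc$min_cells_at_cpm)
}

run_qc <- function(counts, cfg) {
  th <- qc_from_config(cfg)
  s1 <- strip_gene_classes(counts)
  s2 <- filter_cells(s1$counts, th, relaxed = isTRUE(cfg$qc$relaxed))
  s3 <- filter_genes_cpm(s2$counts, th)
  removed <- function(rep_df, axis) {
    data.frame(id = rep_df[[1]], axis = rep(axis, nrow(rep_df)),
               reason = rep_df$reason)
  }
  report <- rbind(removed(s1$report$removed_genes, "gene"),
                  removed(s2$report$removed_cells, "cell"),
                  removed(s3$report$removed_genes, "gene"))
  list(counts = s3$counts, report = report)
}

truth_signatures <- function(truth) {
  signature_set(truth$specific_genes, provenance = "planted truth")
}

log_line <- function(con, ...) {
  msg <- paste0(...)
  writeLines(msg, con)
  message(msg)
}

# deterministic toy interactome over the human orthologs of the simulated
# genes; stands in for user-supplied curated interaction tables
synthesize_interactome <- function(gene_ids, n_edges = 4000,
                                   frac_mapped = 0.9) {
  human <- paste0(toupper(gene_ids), "H")
  n <- length(gene_ids)
  mapped <- sort(sample.int(n, round(frac_mapped * n)))
  orth <- data.frame(mouse_id = gene_ids[mapped],
                     human_id = human[mapped])
  # a few one-to-many mouse genes
  dup <- mapped[seq_len(min(20, length(mapped)))]
  orth <- rbind(orth, data.frame(mouse_id = gene_ids[dup],
                                 human_id = paste0(human[dup], "B")))
  all_h <- unique(orth$human_id)
  a <- sample(all_h, n_edges, replace = TRUE)
  b <- sample(all_h, n_edges, replace = TRUE)
  keep <- a != b
  lo <- pmin(a[keep], b[keep]); hi <- pmax(a[keep], b[keep])
  dd <- !duplicated(paste(lo, hi, sep = "\r"))
  edges <- data.frame(from = lo[dd], to = hi[dd])
  fun_ids <- sample(all_h, round(0.4 * length(all_h)))
  functions <- data.frame(
    human_id = fun_ids,
    class = sample(c("ST", "TF"), length(fun_ids), replace = TRUE))
  # a handful of dual-function genes
  functions <- rbind(functions,
                     data.frame(human_id = fun_ids[seq_len(min(10, length(fun_ids)))],
                                class = ifelse(functions$class[seq_len(min(10, length(fun_ids)))] == "ST",
                                               "TF", "ST")))
  list(edges = edges, orthologs = orth, functions = functions)
}

#' Run an end-to-end analysis workflow on synthetic data
#'
#' Wires the pipeline stages into the three study workflows plus the
#' network stage, writing deterministic TSV outputs, the resolved
#' configuration and a log file to `out_dir`. With a fixed seed the
#' numeric outputs are byte-identical across runs.
#'
#' * `luminal` — simulate basal/LP/ML plus the luminal-intermediate
#'   population, QC, quantile-normalized log2-CPM, ternary scores and
#'   classification, monotone-trend and elevated-intermediate statistics,
#'   leading-logFC MDS. Outputs `ternary.tsv`, `lumint_genes.tsv`,
#'   `lumint_summary.tsv`, `elevated.tsv`, `mds.tsv`, `qc_report.tsv`.
#' * `stages` — simulate bulk replicates of the three cell types, derive
#'   lineage signatures (TREAT at 2/2/1.3, FDR 0.05), rank genes by the
#'   one-way LRT, MDS of samples. Outputs `de_oneway.tsv`,
#'   `signatures.gmt`, `signature_stats.tsv`, `mds.tsv`.
#' * `basal` — simulate basal cells carrying a planted ~5% mixed-lineage
#'   subset, log2-RPKM, mixed-lineage detection. Outputs `mixed.tsv`.
#' * `network` — two-group DE on bulk, ortholog mapping (FDR 0.001),
#'   induced interaction subnetwork, ST/TF classification, SIF/TSV export
#'   under `network/`. Interaction tables come from config paths or, when
#'   unset, a seeded toy interactome.
#'
#' @param config configuration list (see [default_config()]); file paths
#'   accepted via [read_config()]
#' @param workflow one of `"luminal"`, `"stages"`, `"basal"`, `"network"`
#' @param out_dir output directory
#' @return invisibly, a list of the main result objects
#' @export
run_pipeline <- function(config = default_config(),
                         workflow = c("luminal", "stages", "basal",
                                      "network"),
                         out_dir = "mamlin_out") {
  workflow <- match.arg(workflow)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(config, file.path(out_dir, "config_resolved.yaml"))
  logf <- file(file.path(out_dir, "run.log"), open = "wt")
  on.exit(close(logf), add = TRUE)
  log_line(logf, "mamlin ", as.character(utils::packageVersion("mamlin")),
           " workflow=", workflow, " seed=", config$seed)
  cfg_digest <- sum(utf8ToInt(paste(deparse(config), collapse = "")))
  log_line(logf, "config digest ", cfg_digest)
  set.seed(config$seed)
  res <- switch(workflow,
                luminal = wf_luminal(config, out_dir, logf),
                stages = wf_stages(config, out_dir, logf),
                basal = wf_basal(config, out_dir, logf),
                network = wf_network(config, out_dir, logf))
  log_line(logf, "done")
  invisible(res)
}

wf_luminal <- function(cfg, out_dir, logf) {
  design <- default_cell_design(seed = cfg$seed,
                                n_cells = cfg$synthetic$cells$n_cells,
                                with_intermediate = TRUE,
                                with_mixed = FALSE)
  sim <- simulate_cells(design)
  log_line(logf, "simulated ", ncol(sim$counts$counts), " cells")
  qc <- run_qc(sim$counts, cfg)
  write_table(qc$report, file.path(out_dir, "qc_report.tsv"))
  cm <- qc$counts
  log_line(logf, "post-QC ", nrow(cm$counts), " genes x ",
           ncol(cm$counts), " cells")

  lcpm <- to_log2cpm(cm, prior = cfg$normalize$log2cpm_prior)
  qn <- quantile_normalize(lcpm)
  sigs <- truth_signatures(sim$truth)
  scores <- ternary_cell_scores(qn, sigs)
  scores$class <- classify_cells(scores,
                                 intermediate_band =
                                   cfg$lineage$intermediate_band)
  scores$true_label <- unname(sim$truth$cell_labels[scores$sample_id])
  write_table(scores[, setdiff(names(scores), "label")],
              file.path(out_dir, "ternary.tsv"))

  labels <- sim$truth$cell_labels[cm$sample_ids]
  mt <- monotone_fraction(cm, labels, fdr_cut = cfg$trend$fdr_cut,
                          eps = cfg$trend$eps)
  write_table(mt$per_gene, file.path(out_dir, "lumint_genes.tsv"))
  write_table(data.frame(n_de_genes = mt$n_de_genes,
                         n_monotone = mt$n_monotone,
                         fraction_monotone = mt$fraction_monotone),
              file.path(out_dir, "lumint_summary.tsv"))
  el <- elevated_intermediate_genes(cm, labels, ratio = cfg$trend$ratio,
                                    fdr_cut = cfg$trend$fdr_cut)
  write_table(el$genes, file.path(out_dir, "elevated.tsv"))
  log_line(logf, "monotone fraction ",
           formatC(mt$fraction_monotone, format = "g", digits = 6))

  d <- leading_logfc_distances(lcpm, k_top = cfg$structure$k_top)
  coords <- classical_mds(d, dims = cfg$structure$dims)
  write_table(data.frame(sample_id = rownames(coords), coords,
                         label = unname(labels)),
              file.path(out_dir, "mds.tsv"))
  list(scores = scores, monotone = mt, elevated = el, mds = coords,
       qc = qc$report)
}

wf_stages <- function(cfg, out_dir, logf) {
  design <- default_bulk_design(seed = cfg$seed,
                                n_reps = cfg$synthetic$bulk$n_reps,
                                log2fc = cfg$synthetic$bulk$log2fc,
                                phi = cfg$synthetic$bulk$phi)
  sim <- simulate_bulk(design)
  log_line(logf, "simulated ", ncol(sim$counts$counts),
           " bulk libraries")
  disp <- estimate_dispersions(sim$counts,
                               shrink_weight = cfg$de$shrink_weight)
  log_line(logf, "common dispersion ",
           formatC(disp$common_phi, format = "g", digits = 6))
  sigs <- derive_signatures(sim$counts, disp = disp,
                            fdr_cut = cfg$de$fdr_cut)
  write_gene_sets(sigs, file.path(out_dir, "signatures.gmt"))
  if (!is.null(sigs$stats))
    write_table(sigs$stats, file.path(out_dir, "signature_stats.tsv"))
  de <- lrt_de(sim$counts, disp = disp)
  de <- de[order(de$fdr, -abs(de$log2fc), de$gene_id), ]
  write_table(de, file.path(out_dir, "de_oneway.tsv"))

  lcpm <- to_log2cpm(sim$counts, prior = cfg$normalize$log2cpm_prior)
  d <- leading_logfc_distances(lcpm, k_top = cfg$structure$k_top)
  coords <- classical_mds(d, dims = cfg$structure$dims)
  write_table(data.frame(sample_id = rownames(coords), coords,
                         group = sample_groups(sim$counts)),
              file.path(out_dir, "mds.tsv"))
  list(signatures = sigs, de = de, mds = coords, disp = disp)
}

wf_basal <- function(cfg, out_dir, logf) {
  design <- default_cell_design(seed = cfg$seed,
                                n_cells = cfg$synthetic$cells$n_cells,
                                with_intermediate = FALSE,
                                with_mixed = TRUE)
  sim <- simulate_cells(design)
  basal_cells <- names(sim$truth$cell_labels)[
    sim$truth$cell_labels == "basal"]
  cm <- sim$counts[, basal_cells]
  log_line(logf, "sorted ", ncol(cm$counts), " basal cells (",
           length(sim$truth$mixed_cells), " planted mixed)")
  rpkm <- to_log2rpkm(cm, prior = cfg$normalize$rpkm_prior,
                      scale_prior = cfg$normalize$scale_prior)
  sigs <- truth_signatures(sim$truth)
  calls <- detect_mixed_lineage(
    rpkm, host_class = "basal", sigs,
    min_foreign_genes = cfg$lineage$min_foreign_genes,
    detect_log2rpkm = log2(cfg$lineage$detect_rpkm),
    host_dominance = cfg$lineage$host_dominance)
  calls$planted_mixed <- calls$sample_id %in% sim$truth$mixed_cells
  write_table(calls, file.path(out_dir, "mixed.tsv"))
  log_line(logf, "called ", sum(calls$is_mixed), " mixed cells")
  list(calls = calls, truth = sim$truth)
}

wf_network <- function(cfg, out_dir, logf) {
  design <- default_bulk_design(seed = cfg$seed,
                                n_reps = cfg$synthetic$bulk$n_reps,
                                log2fc = cfg$synthetic$bulk$log2fc,
                                phi = cfg$synthetic$bulk$phi)
  sim <- simulate_bulk(design)
  groups <- sample_groups(sim$counts)
  keep <- groups %in% c("basal", "LP")
  sub <- sim$counts[, which(keep)]
  disp <- estimate_dispersions(sub, shrink_weight = cfg$de$shrink_weight)
  de <- lrt_de(sub, disp = disp)

  nets <- if (!is.null(cfg$network$edges))
    read_network_tables(cfg$network$edges, cfg$network$orthologs,
                        cfg$network$functions)
  else
    synthesize_interactome(sim$counts$gene_ids)
  mapped <- map_orthologs(de, nets$orthologs,
                          fdr_cut = cfg$de$network_fdr)
  log_line(logf, nrow(mapped), " mapped DE gene rows, ",
           length(attr(mapped, "unmapped")), " unmapped")
  net <- build_de_subnetwork(mapped, nets$edges)
  net <- classify_node_function(net, nets$functions)
  export_network(net, file.path(out_dir, "network"))
  export_network(net$st_tf_view, file.path(out_dir, "network_st_tf"))
  write_table(data.frame(mouse_id = attr(mapped, "unmapped")),
              file.path(out_dir, "unmapped.tsv"))
  list(network = net, mapped = mapped, de = de)
}
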