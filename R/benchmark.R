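#' Planted-edge recovery benchmark for one simulated study
#'
#' Simulates one full study (gene models, peaks, expression) under the
#' reference conditions, runs binding and regulation calling, and scores
#' the calls against the planted truth. An edge counts as recovered only
#' when TF, gene, and direction all match the planted edge.
#'
#' @param seed Master seed for the simulated study.
#' @param noise_sd Expression noise sd (default 0.25; 0 gives the
#'   zero-noise identifiability setting).
#' @param n_genes Number of simulated genes.
#' @param alpha Significance level for regulation calling.
#' @return List with counts (`tp`, `fp`, `fn` for single-TF edges;
#'   `syn_tp`, `syn_fn` for synergy edges; `syn_leak`, synergy calls for
#'   genes significant in a single mutant -- always 0 by construction of
#'   the caller), and the `regulation` and `truth` tables.
#' @export
edge_recovery <- function(seed, noise_sd = 0.25, n_genes = 400L, alpha = 0.05) {
  cfg <- default_sim_config(n_genes = n_genes, seed = seed)
  cfg$noise_sd <- noise_sd
  truth <- make_planted_truth(cfg)
  design <- experiment_design()
  gm <- generate_gene_models(cfg$n_genes, cfg$n_chroms, cfg$min_gap_bp,
                             cfg$chrom_length_bp, cfg$gene_length_range,
                             seed = cfg$seed)
  pk <- generate_peaks(gm, truth$binding, cfg$decoy_per_tf, cfg$window_bp,
                       cfg$peak_width_range, cfg$chrom_length_bp,
                       seed = cfg$seed)
  expr <- generate_expression(design, truth, cfg$probes_per_gene, cfg$noise_sd,
                              cfg$baseline, cfg$effect_log2fc, seed = cfg$seed)
  binding <- call_binding(pk, gm, window_bp = cfg$window_bp)
  mut <- mutant_summaries(expr$matrix, expr$sample_sheet, expr$probe_map,
                          alpha = alpha, verbose = FALSE)
  de <- mutant_de_table(mut)
  singles <- call_regulation(binding, de, alpha = alpha)
  synergy <- call_synergy(binding, de, tf_pair = "Tbr1+Tbr2", alpha = alpha)
  regulation <- combine_regulation(singles, synergy)

  key <- function(tf, gene, mode) paste(tf, gene, mode)
  tru <- truth$regulation
  tru_single <- tru[tru$mode %in% c("activates", "represses"), , drop = FALSE]
  pred_single <- regulation[regulation$mode %in% c("activates", "represses"), ,
                            drop = FALSE]
  tk <- key(tru_single$tf, tru_single$gene_id, tru_single$mode)
  pk_ <- key(pred_single$tf, pred_single$gene_id, pred_single$mode)
  tp <- sum(pk_ %in% tk)
  tru_syn <- tru[startsWith(tru$mode, "synergistic"), , drop = FALSE]
  pred_syn <- regulation[startsWith(regulation$mode, "synergistic"), ,
                         drop = FALSE]
  stk <- key(tru_syn$tf, tru_syn$gene_id, tru_syn$mode)
  spk <- key(pred_syn$tf, pred_syn$gene_id, pred_syn$mode)
  # synergy calls for genes with a significant single-mutant result would
  # violate the exclusivity rule; count them (the caller forbids them)
  syn_leak <- 0L
  for (g in pred_syn$gene_id) {
    d <- de[de$tf %in% c("Tbr1", "Tbr2") & de$gene_id == g, , drop = FALSE]
    if (any(!is.na(d$p_value) & d$p_value < alpha)) syn_leak <- syn_leak + 1L
  }
  list(
    tp = tp, fp = nrow(pred_single) - tp, fn = nrow(tru_single) - tp,
    syn_tp = sum(spk %in% stk), syn_fn = sum(!stk %in% spk),
    syn_leak = syn_leak,
    regulation = regulation, truth = truth, binding = binding
  )
}

#' Classifier recovery benchmark for one simulated study
#'
#' Simulates lineage-sort expression plus zonal and rostrocaudal profiles
#' and scores the cell-type and gradient classifiers against the planted
#' labels.
#'
#' @param seed Master seed.
#' @param noise_sd Expression and profile noise sd (0 for the zero-noise
#'   setting; the default uses the reference conditions).
#' @param n_genes Number of simulated genes.
#' @return List with `celltype_accuracy`, `gradient_accuracy`, and the
#'   call tables.
#' @export
classification_recovery <- function(seed, noise_sd = NULL, n_genes = 400L) {
  cfg <- default_sim_config(n_genes = n_genes, seed = seed)
  if (!is.null(noise_sd)) {
    cfg$noise_sd <- noise_sd
    cfg$zonal_noise_sd <- noise_sd
    cfg$gradient_noise_sd <- noise_sd
  }
  truth <- make_planted_truth(cfg)
  design <- experiment_design()
  expr <- generate_expression(design, truth, cfg$probes_per_gene, cfg$noise_sd,
                              cfg$baseline, cfg$effect_log2fc, seed = cfg$seed)
  zonal <- generate_zonal_profiles(truth, cfg$detect_floor, cfg$zonal_noise_sd,
                                   cfg$zone_on_intensity, cfg$zone_off_intensity,
                                   seed = cfg$seed)
  regional <- generate_gradient_profiles(truth, cfg$n_bins, cfg$gradient_slope,
                                         cfg$gradient_base, cfg$gradient_noise_sd,
                                         seed = cfg$seed)
  lineage <- lineage_enrichment(expr$matrix, expr$sample_sheet, expr$probe_map,
                                alpha = cfg$alpha, verbose = FALSE)
  annotations <- data.frame(gene_id = truth$celltype$gene_id,
                            cortex_specific = truth$celltype$cortex_specific,
                            stringsAsFactors = FALSE)
  celltype <- classify_cell_types(lineage, zonal, annotations,
                                  detect_floor = cfg$detect_floor,
                                  dominance_frac = cfg$dominance_frac)
  gradients <- classify_gradients(regional, rho_threshold = cfg$rho_threshold,
                                  alpha = cfg$alpha, n_perm = cfg$n_perm,
                                  seed = cfg$seed)
  ct <- merge(celltype, truth$celltype, by = "gene_id")
  gr <- merge(gradients, truth$celltype, by = "gene_id")
  list(
    celltype_accuracy = mean(ct$label == ct$cell_type_label),
    gradient_accuracy = mean(gr$direction == gr$gradient_label),
    celltype = celltype, gradients = gradients, truth = truth
  )
}
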