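#' Generate a log2 expression matrix with planted effects
#'
#' Simulates probe-level log2 intensities for the full sample layout of an
#' [experiment_design()]: per-gene and per-probe baseline offsets, planted
#' mutant effects, planted lineage-sort enrichment, and i.i.d. Gaussian
#' noise. Sign conventions follow loss-of-function logic: a gene *activated*
#' by a TF loses expression in that TF's mutant (log2FC = -effect relative
#' to control), a *repressed* gene is derepressed (+effect). Genes regulated
#' synergistically by Tbr1 and Tbr2 shift only in the double mutant.
#' Genes whose planted cell-type label is `conflicted` receive opposite-sign
#' lineage effects on alternating probes, so probe-level lineage enrichment
#' disagrees within the gene.
#'
#' @param design An `ef_design` object.
#' @param truth An `ef_truth` object (see [make_planted_truth()]).
#' @param probes_per_gene Probes per gene (>= 1; conflicted genes need >= 2).
#' @param noise_sd Gaussian noise sd on log2 intensities (>= 0).
#' @param baseline Grand mean log2 intensity.
#' @param effect_log2fc Planted lineage-enrichment magnitude; mutant effects
#'   use the per-edge `effect_log2fc` from the truth table.
#' @param seed RNG seed.
#' @return List with `matrix` (probes x samples), `sample_sheet`, and
#'   `probe_map` (probe_id, gene_id).
#' @export
generate_expression <- function(design, truth, probes_per_gene = 2L,
                                noise_sd = 0.25, baseline = 8,
                                effect_log2fc = 0.75, seed = 1L) {
  stopifnot(inherits(design, "ef_design"))
  check_truth(truth)
  if (probes_per_gene < 1L) stop_ef("probes_per_gene must be >= 1")
  if (noise_sd < 0) stop_ef("noise_sd must be >= 0")
  if (probes_per_gene < 2L && any(truth$celltype$cell_type_label == "conflicted")) {
    stop_ef("conflicted genes require probes_per_gene >= 2")
  }
  sheet <- design_sample_sheet(design)
  genes <- truth$celltype$gene_id
  n_genes <- length(genes)
  probe_map <- data.frame(
    probe_id = sprintf("%s_p%d", rep(genes, each = probes_per_gene),
                       rep(seq_len(probes_per_gene), n_genes)),
    gene_id = rep(genes, each = probes_per_gene),
    stringsAsFactors = FALSE
  )
  gt_map <- genotype_tf_map()
  reg <- truth$regulation
  labels <- setNames(truth$celltype$cell_type_label, truth$celltype$gene_id)
  gfp_neg_labels <- c("RGP", "mixed")

  # planted mutant effect per (gene, genotype), on the mutant samples
  effect_of <- function(gene, genotype) {
    tfs <- gt_map[[genotype]]
    if (is.null(tfs)) return(0)
    eff <- 0
    single <- reg[reg$gene_id == gene & reg$tf %in% tfs &
                    reg$mode %in% c("activates", "represses"), , drop = FALSE]
    if (nrow(single)) {
      eff <- eff + sum(ifelse(single$mode == "activates", -1, 1) * single$effect_log2fc)
    }
    if (genotype == "tbr1_tbr2_dko") {
      syn <- reg[reg$gene_id == gene & reg$tf == "Tbr1+Tbr2", , drop = FALSE]
      if (nrow(syn)) {
        eff <- eff + sum(ifelse(syn$mode == "synergistic_activates", -1, 1) *
                           syn$effect_log2fc)
      }
    }
    eff
  }

  with_seed(sub_seed(seed, "expression"), {
    gene_off <- rnorm(n_genes, 0, 1)
    names(gene_off) <- genes
    probe_off <- rnorm(nrow(probe_map), 0, 0.5)
    n_probes <- nrow(probe_map)
    n_samples <- nrow(sheet)
    mat <- matrix(baseline, nrow = n_probes, ncol = n_samples,
                  dimnames = list(probe_map$probe_id, sheet$sample_id))
    mat <- mat + gene_off[probe_map$gene_id] + probe_off

    # mutant effects: per genotype column block, per gene row block
    mutant_genotypes <- intersect(unique(sheet$genotype), names(gt_map))
    reg_genes <- unique(reg$gene_id)
    for (gt in mutant_genotypes) {
      cols <- which(sheet$genotype == gt & sheet$lineage_fraction == "bulk")
      if (!length(cols)) next
      for (gene in reg_genes) {
        e <- effect_of(gene, gt)
        if (e != 0) {
          rws <- which(probe_map$gene_id == gene)
          mat[rws, cols] <- mat[rws, cols] + e
        }
      }
    }

    # lineage-sort enrichment
    pos_cols <- which(sheet$lineage_fraction == "GFP_pos")
    neg_cols <- which(sheet$lineage_fraction == "GFP_neg")
    if (length(pos_cols) && length(neg_cols)) {
      for (i in seq_len(n_genes)) {
        lab <- labels[[genes[i]]]
        if (lab == "none") next
        rws <- which(probe_map$gene_id == genes[i])
        if (lab == "conflicted") {
          odd <- rws[seq_along(rws) %% 2L == 1L]
          even <- setdiff(rws, odd)
          mat[odd, pos_cols] <- mat[odd, pos_cols] + effect_log2fc
          mat[even, neg_cols] <- mat[even, neg_cols] + effect_log2fc
        } else if (lab %in% gfp_neg_labels) {
          mat[rws, neg_cols] <- mat[rws, neg_cols] + effect_log2fc
        } else {
          mat[rws, pos_cols] <- mat[rws, pos_cols] + effect_log2fc
        }
      }
    }

    if (noise_sd > 0) {
      mat <- mat + matrix(rnorm(n_probes * n_samples, 0, noise_sd),
                          nrow = n_probes)
    }
    list(matrix = mat, sample_sheet = sheet, probe_map = probe_map)
  })
}

# Canonical zone-intensity template per cell-type label. Neuron labels are
# expressed from their initial zone onward (apical -> pial persistence).
zone_template <- function(label, on = 3, off = 0.1) {
  zones <- switch(label,
    "RGP" = "VZ",
    "aIP" = "VZ",
    "bIP" = "SVZ",
    "aIP+bIP" = c("VZ", "SVZ"),
    "N-vz" = c("VZ", "SVZ", "IZ", "CP"),
    "N-svz" = c("SVZ", "IZ", "CP"),
    "N-iz" = c("IZ", "CP"),
    "N-cp" = "CP",
    "PN-iz" = c("IZ", "CP"),
    "PN-cp" = "CP",
    "mixed" = c("SVZ", "IZ"),
    "conflicted" = c("VZ", "SVZ"),
    "none" = character(0),
    stop_ef("unknown cell-type label: ", label)
  )
  ifelse(CORTICAL_ZONES %in% zones, on, off)
}

#' Generate zonal (VZ/SVZ/IZ/CP) expression profiles
#'
#' Each gene's planted cell-type label is realised as its canonical
#' zone-intensity template (for example RGP genes are expressed in VZ only;
#' aIP+bIP genes are bilaminar in VZ and SVZ; neuron-class genes are
#' expressed from their initial zone through the cortical plate) plus
#' Gaussian noise, truncated at zero.
#'
#' @param truth An `ef_truth` object.
#' @param detect_floor Intensity below which a zone is called undetected.
#' @param noise_sd Gaussian noise sd (>= 0).
#' @param on_intensity,off_intensity Template intensity in expressing and
#'   non-expressing zones.
#' @param seed RNG seed.
#' @return Data frame with columns `gene_id`, `VZ`, `SVZ`, `IZ`, `CP`.
#' @export
generate_zonal_profiles <- function(truth, detect_floor = 0.5, noise_sd = 0.25,
                                    on_intensity = 3, off_intensity = 0.1,
                                    seed = 1L) {
  check_truth(truth)
  if (noise_sd < 0) stop_ef("noise_sd must be >= 0")
  ct <- truth$celltype
  with_seed(sub_seed(seed, "zonal"), {
    tmpl <- t(vapply(ct$cell_type_label, zone_template, numeric(4),
                     on = on_intensity, off = off_intensity))
    if (noise_sd > 0) {
      tmpl <- tmpl + matrix(rnorm(length(tmpl), 0, noise_sd), nrow = nrow(tmpl))
    }
    tmpl <- pmax(tmpl, 0)
    out <- data.frame(gene_id = ct$gene_id, tmpl, stringsAsFactors = FALSE)
    names(out) <- c("gene_id", CORTICAL_ZONES)
    rownames(out) <- NULL
    out
  })
}

#' Generate rostrocaudal gradient profiles
#'
#' Realises each gene's planted gradient label over `n_bins` ordered
#' rostrocaudal bins (bin 1 = rostral pole): `high_rostral` genes decrease
#' with bin index, `high_caudal` genes increase, `none` genes are flat.
#'
#' @param truth An `ef_truth` object.
#' @param n_bins Number of rostrocaudal bins (>= 3).
#' @param slope Intensity change per bin for graded genes.
#' @param base Baseline intensity of the lowest bin.
#' @param noise_sd Gaussian noise sd (>= 0).
#' @param zone_context Zone label attached to every profile row.
#' @param seed RNG seed.
#' @return Data frame with columns `gene_id`, `zone_context`,
#'   `bin_1` ... `bin_<n_bins>`.
#' @export
generate_gradient_profiles <- function(truth, n_bins = 7L, slope = 1,
                                       base = 1, noise_sd = 0.25,
                                       zone_context = "VZ/SVZ", seed = 1L) {
  check_truth(truth)
  if (n_bins < 3L) stop_ef("n_bins must be >= 3 (trend undefined otherwise)")
  if (noise_sd < 0) stop_ef("noise_sd must be >= 0")
  ct <- truth$celltype
  idx <- seq_len(n_bins) - 1L
  with_seed(sub_seed(seed, "gradient"), {
    prof <- t(vapply(ct$gradient_label, function(gl) {
      switch(gl,
        high_caudal = base + slope * idx,
        high_rostral = base + slope * rev(idx),
        none = rep(base, n_bins),
        stop_ef("unknown gradient label: ", gl)
      )
    }, numeric(n_bins)))
    if (noise_sd > 0) {
      prof <- prof + matrix(rnorm(length(prof), 0, noise_sd), nrow = nrow(prof))
    }
    prof <- pmax(prof, 0)
    out <- data.frame(gene_id = ct$gene_id, zone_context = zone_context,
                      prof, stringsAsFactors = FALSE)
    names(out) <- c("gene_id", "zone_context", sprintf("bin_%d", seq_len(n_bins)))
    rownames(out) <- NULL
    out
  })
}
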