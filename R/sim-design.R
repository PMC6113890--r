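#' Experiment design for the simulated microarray study
#'
#' Describes the sample layout that the expression generator emulates: two
#' mutant microarray experiments (MA1, MA2) sharing the Tbr1-null and
#' Tbr2-conditional genotypes, with the Tbr1/Tbr2 double mutant present only
#' on MA2; a separate single-experiment Pax6-null contrast (P1); and a
#' lineage-sort experiment (LIN) comparing Tbr2-GFP+ and Tbr2-GFP- sorted
#' fractions. Default replicate counts for the mutant genotypes are
#' 3 control, 4 Tbr1 KO, 2 Tbr2 cKO, and 3 Tbr1/2 dKO.
#'
#' @param experiments Named list; one element per experiment id, each a named
#'   integer vector of replicate counts per genotype.
#' @param lineage Named integer vector of replicate counts for the sorted
#'   fractions (`GFP_pos`, `GFP_neg`).
#' @param lineage_experiment Experiment id used for the lineage-sort samples.
#' @return An object of class `ef_design`.
#' @examples
#' d <- experiment_design()
#' design_sample_sheet(d)[1:4, ]
#' @export
experiment_design <- function(
    experiments = list(
      MA1 = c(control = 3L, tbr1_ko = 4L, tbr2_cko = 2L),
      MA2 = c(control = 3L, tbr1_ko = 4L, tbr2_cko = 2L, tbr1_tbr2_dko = 3L),
      P1  = c(control = 3L, pax6_ko = 3L)
    ),
    lineage = c(GFP_pos = 4L, GFP_neg = 4L),
    lineage_experiment = "LIN") {
  if (anyDuplicated(names(experiments)) > 0L) {
    stop_ef("experiment ids must be unique")
  }
  for (ex in names(experiments)) {
    reps <- experiments[[ex]]
    if (is.null(names(reps)) || any(!nzchar(names(reps)))) {
      stop_ef("replicate counts in experiment ", ex, " must be named by genotype")
    }
    if (any(reps < 2L)) {
      stop_ef("every genotype needs >= 2 replicates (experiment ", ex, ")")
    }
    unknown <- setdiff(names(reps), names(genotype_tf_map()))
    unknown <- setdiff(unknown, "control")
    if (length(unknown)) {
      stop_ef("unknown genotype label(s): ", paste(unknown, collapse = ", "))
    }
  }
  if (any(lineage < 2L)) stop_ef("lineage fractions need >= 2 replicates")
  if (lineage_experiment %in% names(experiments)) {
    stop_ef("lineage_experiment id collides with a mutant experiment id")
  }
  structure(
    list(
      experiments = experiments,
      lineage = lineage,
      lineage_experiment = lineage_experiment
    ),
    class = "ef_design"
  )
}

# Map mutant genotype labels to the disrupted TF(s).
genotype_tf_map <- function() {
  list(
    pax6_ko = "Pax6",
    tbr1_ko = "Tbr1",
    tbr2_cko = "Tbr2",
    tbr1_tbr2_dko = c("Tbr1", "Tbr2")
  )
}

#' Expand an experiment design into a sample sheet
#'
#' @param design An `ef_design` object.
#' @return A data frame with columns `sample_id`, `genotype`, `experiment`,
#'   `lineage_fraction`, and `replicate`. Bulk mutant samples carry
#'   `lineage_fraction = "bulk"`.
#' @export
design_sample_sheet <- function(design) {
  stopifnot(inherits(design, "ef_design"))
  rows <- list()
  for (ex in names(design$experiments)) {
    reps <- design$experiments[[ex]]
    for (gt in names(reps)) {
      r <- seq_len(reps[[gt]])
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("%s_%s_%d", ex, gt, r),
        genotype = gt,
        experiment = ex,
        lineage_fraction = "bulk",
        replicate = r,
        stringsAsFactors = FALSE
      )
    }
  }
  for (fr in names(design$lineage)) {
    r <- seq_len(design$lineage[[fr]])
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sprintf("%s_%s_%d", design$lineage_experiment, fr, r),
      genotype = "control",
      experiment = design$lineage_experiment,
      lineage_fraction = fr,
      replicate = r,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default simulation configuration
#'
#' One list holding every tunable of the synthetic-data module, with defaults
#' chosen as the package's reference study conditions: 400 genes on 5
#' chromosomes, two probes per gene, planted log2 effects of 0.75 with
#' Gaussian noise (sd 0.25), a 50 kb binding window, and the mutant replicate
#' counts of [experiment_design()].
#'
#' @param n_genes Number of simulated genes.
#' @param seed Master seed; each generator derives a fixed sub-seed from it.
#' @return A list of class `ef_sim_config`.
#' @export
default_sim_config <- function(n_genes = 400L, seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    n_genes = as.integer(n_genes),
    n_chroms = 5L,
    chrom_length_bp = 4e7,
    min_gap_bp = 120000L,
    gene_length_range = c(1000L, 100000L),
    probes_per_gene = 2L,
    baseline = 8,
    effect_log2fc = 0.75,
    noise_sd = 0.25,
    window_bp = 50000L,
    decoy_per_tf = 30L,
    peak_width_range = c(200L, 1000L),
    detect_floor = 0.5,
    zone_on_intensity = 3,
    zone_off_intensity = 0.1,
    zonal_noise_sd = 0.25,
    n_bins = 7L,
    gradient_slope = 1,
    gradient_base = 1,
    gradient_noise_sd = 0.25,
    dominance_frac = 0.5,
    rho_threshold = 0.8,
    alpha = 0.05,
    n_perm = 10000L,
    tf_order = c("Pax6", "Tbr2", "Tbr1"),
    # planted composition (counts scale with n_genes if it differs from 400)
    label_counts = c(
      "RGP" = 40, "aIP" = 20, "bIP" = 25, "aIP+bIP" = 25,
      "N-vz" = 20, "N-svz" = 20, "N-iz" = 20, "N-cp" = 15,
      "PN-iz" = 15, "PN-cp" = 15, "mixed" = 15, "conflicted" = 20
    ),
    gradient_counts = c(high_rostral = 30, high_caudal = 40),
    single_edge_counts = c(Pax6 = 13, Tbr2 = 14, Tbr1 = 13),
    n_synergy = 4L,
    bound_only_per_tf = 8L
  )
  class(cfg) <- "ef_sim_config"
  cfg
}

#' Build the planted ground truth for a simulation
#'
#' Assigns each simulated gene a cell-type label, a rostrocaudal gradient
#' label, and (for a configured subset) planted regulation by Pax6, Tbr2,
#' Tbr1, or the Tbr1/Tbr2 pair. The truth tables are internally consistent:
#' every regulated gene is bound by its TF, and every synergistic gene is
#' bound by both TFs. Additional "bound only" genes carry TF binding without
#' planted differential expression.
#'
#' @param config An `ef_sim_config` list (see [default_sim_config()]).
#' @return A list of class `ef_truth` with data frames `celltype`
#'   (gene_id, cell_type_label, cortex_specific, gradient_label),
#'   `regulation` (tf, gene_id, mode, effect_log2fc), and `binding`
#'   (tf, gene_id, bound).
#' @export
make_planted_truth <- function(config = default_sim_config()) {
  n <- config$n_genes
  gene_ids <- sprintf("g%04d", seq_len(n))
  scale <- n / 400
  lab_counts <- setNames(pmax(0L, as.integer(round(config$label_counts * scale))),
                         names(config$label_counts))
  if (sum(lab_counts) > n) stop_ef("label counts exceed n_genes")
  grad_counts <- setNames(pmax(0L, as.integer(round(config$gradient_counts * scale))),
                          names(config$gradient_counts))
  edge_counts <- pmax(0L, as.integer(round(config$single_edge_counts * scale)))
  names(edge_counts) <- names(config$single_edge_counts)
  n_syn <- as.integer(round(config$n_synergy * scale))
  n_bound_only <- as.integer(round(config$bound_only_per_tf * scale))

  with_seed(sub_seed(config$seed, "truth"), {
    perm <- sample(gene_ids)
    labels <- rep("none", n)
    names(labels) <- perm
    idx <- 1L
    for (lab in names(lab_counts)) {
      k <- lab_counts[[lab]]
      if (k > 0L) {
        labels[idx:(idx + k - 1L)] <- lab
        idx <- idx + k
      }
    }
    celltype <- data.frame(
      gene_id = perm,
      cell_type_label = unname(labels),
      cortex_specific = unname(startsWith(labels, "PN-")),
      stringsAsFactors = FALSE
    )

    gperm <- sample(gene_ids)
    glabels <- rep("none", n)
    names(glabels) <- gperm
    gidx <- 1L
    for (gl in names(grad_counts)) {
      k <- grad_counts[[gl]]
      if (k > 0L) {
        glabels[gidx:(gidx + k - 1L)] <- gl
        gidx <- gidx + k
      }
    }
    celltype$gradient_label <- unname(glabels[celltype$gene_id])

    # Regulation targets: disjoint gene sets per TF, plus synergy genes
    # (bound by both Tbr1 and Tbr2, shifted only in the double mutant) and
    # bound-only genes (binding without expression change).
    need <- sum(edge_counts) + n_syn + 3L * n_bound_only
    if (need > n) stop_ef("regulation truth needs more genes than available")
    pool <- sample(gene_ids, need)
    take <- function(k) {
      if (k == 0L) return(character(0))
      out <- pool[seq_len(k)]
      pool <<- pool[-seq_len(k)]
      out
    }
    reg_rows <- list()
    bind_rows <- list()
    for (tf in names(edge_counts)) {
      targets <- take(edge_counts[[tf]])
      mode <- ifelse(seq_along(targets) %% 2L == 1L, "activates", "represses")
      reg_rows[[tf]] <- data.frame(
        tf = tf, gene_id = targets, mode = mode,
        effect_log2fc = config$effect_log2fc, stringsAsFactors = FALSE
      )
      bind_rows[[tf]] <- data.frame(
        tf = tf, gene_id = targets, bound = TRUE, stringsAsFactors = FALSE
      )
    }
    syn_targets <- take(n_syn)
    if (n_syn > 0L) {
      syn_mode <- ifelse(seq_along(syn_targets) %% 2L == 1L,
                         "synergistic_activates", "synergistic_represses")
      reg_rows[["synergy"]] <- data.frame(
        tf = "Tbr1+Tbr2", gene_id = syn_targets, mode = syn_mode,
        effect_log2fc = config$effect_log2fc, stringsAsFactors = FALSE
      )
      bind_rows[["syn1"]] <- data.frame(
        tf = "Tbr1", gene_id = syn_targets, bound = TRUE, stringsAsFactors = FALSE
      )
      bind_rows[["syn2"]] <- data.frame(
        tf = "Tbr2", gene_id = syn_targets, bound = TRUE, stringsAsFactors = FALSE
      )
    }
    for (tf in c("Pax6", "Tbr2", "Tbr1")) {
      if (n_bound_only > 0L) {
        bo <- take(n_bound_only)
        bind_rows[[paste0("bo_", tf)]] <- data.frame(
          tf = tf, gene_id = bo, bound = TRUE, stringsAsFactors = FALSE
        )
      }
    }
    regulation <- do.call(rbind, reg_rows)
    binding <- unique(do.call(rbind, bind_rows))
    rownames(regulation) <- rownames(binding) <- NULL
    ord <- order(celltype$gene_id)
    celltype <- celltype[ord, , drop = FALSE]
    rownames(celltype) <- NULL
    structure(
      list(celltype = celltype, regulation = regulation, binding = binding),
      class = "ef_truth"
    )
  })
}

# Internal consistency check used by generators and tests.
check_truth <- function(truth) {
  stopifnot(inherits(truth, "ef_truth"))
  reg <- truth$regulation
  bnd <- truth$binding
  key <- function(tf, gene) paste(tf, gene, sep = "\r")
  bound_keys <- key(bnd$tf[bnd$bound], bnd$gene_id[bnd$bound])
  for (i in seq_len(nrow(reg))) {
    tfs <- if (grepl("+", reg$tf[i], fixed = TRUE)) {
      strsplit(reg$tf[i], "+", fixed = TRUE)[[1]]
    } else {
      reg$tf[i]
    }
    if (!all(key(tfs, reg$gene_id[i]) %in% bound_keys)) {
      stop_ef("truth inconsistency: ", reg$tf[i], " regulates ", reg$gene_id[i],
              " without binding")
    }
  }
  bad <- setdiff(truth$celltype$cell_type_label, CELLTYPE_LABELS)
  if (length(bad)) stop_ef("unknown cell-type label(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(truth$celltype$gradient_label, GRADIENT_LABELS)
  if (length(bad)) stop_ef("unknown gradient label(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}
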