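#' Default end-to-end run configuration
#'
#' Bundles the simulation configuration with the analysis thresholds: the
#' significance level (alpha = 0.05, raw p-values, strict inequality), the
#' 50 kb binding window, the zonal dominance fraction, the gradient rho
#' threshold, and the cascade TF ordering.
#'
#' @param seed Master seed for the run.
#' @param n_genes Number of simulated genes.
#' @return List of class `ef_config`.
#' @export
default_config <- function(seed = 1L, n_genes = 400L) {
  cfg <- list(
    seed = as.integer(seed),
    sim = default_sim_config(n_genes = n_genes, seed = seed),
    alpha = 0.05,
    window_bp = 50000L,
    detect_floor = 0.5,
    dominance_frac = 0.5,
    rho_threshold = 0.8,
    n_perm = 10000L,
    tf_order = c("Pax6", "Tbr2", "Tbr1")
  )
  class(cfg) <- "ef_config"
  cfg
}

validate_config <- function(config) {
  if (!inherits(config, "ef_config")) stop_ef("config must be an ef_config")
  if (config$alpha <= 0 || config$alpha >= 1) stop_ef("alpha must be in (0, 1)")
  if (config$window_bp < 0) stop_ef("window_bp must be >= 0")
  if (config$dominance_frac <= 0 || config$dominance_frac > 1) {
    stop_ef("dominance_frac must be in (0, 1]")
  }
  if (config$rho_threshold < 0 || config$rho_threshold > 1) {
    stop_ef("rho_threshold must be in [0, 1]")
  }
  invisible(config)
}

#' Generate and write all synthetic pipeline inputs
#'
#' Runs every generator of the synthetic-data module under the master seed
#' and writes the standard input files: gene models (BED6), one peak BED
#' per TF, the expression matrix, sample sheet, and probe map (TSV), zonal
#' and rostrocaudal profiles (TSV), the planted truth tables (TSV), and the
#' generation config (YAML).
#'
#' @param config An `ef_config` (see [default_config()]).
#' @param outdir Output directory, created if needed.
#' @param verbose Emit progress messages.
#' @return Invisibly, a list with the in-memory objects (`gene_models`,
#'   `peaks`, `expression`, `truth`, `zonal`, `regional`, `design`).
#' @export
simulate_inputs <- function(config = default_config(), outdir, verbose = TRUE) {
  validate_config(config)
  sim <- config$sim
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  design <- experiment_design()
  truth <- make_planted_truth(sim)
  ef_log("generating gene models", verbose = verbose)
  gm <- generate_gene_models(sim$n_genes, sim$n_chroms, sim$min_gap_bp,
                             sim$chrom_length_bp, sim$gene_length_range,
                             seed = sim$seed)
  ef_log("generating peaks", verbose = verbose)
  pk <- generate_peaks(gm, truth$binding, sim$decoy_per_tf, sim$window_bp,
                       sim$peak_width_range, sim$chrom_length_bp,
                       seed = sim$seed)
  ef_log("generating expression", verbose = verbose)
  expr <- generate_expression(design, truth, sim$probes_per_gene,
                              sim$noise_sd, sim$baseline, sim$effect_log2fc,
                              seed = sim$seed)
  zonal <- generate_zonal_profiles(truth, sim$detect_floor, sim$zonal_noise_sd,
                                   sim$zone_on_intensity, sim$zone_off_intensity,
                                   seed = sim$seed)
  regional <- generate_gradient_profiles(truth, sim$n_bins, sim$gradient_slope,
                                         sim$gradient_base, sim$gradient_noise_sd,
                                         seed = sim$seed)
  write_gene_models_bed(gm, file.path(outdir, "genes.bed"))
  for (tf in unique(pk$tf)) {
    write_peaks_bed(pk[pk$tf == tf, , drop = FALSE],
                    file.path(outdir, sprintf("peaks_%s.bed", tf)))
  }
  write_expression_matrix(expr$matrix, file.path(outdir, "expression.tsv"))
  write_tsv(expr$sample_sheet, file.path(outdir, "samples.tsv"))
  write_tsv(expr$probe_map, file.path(outdir, "probe_map.tsv"))
  write_tsv(zonal, file.path(outdir, "zonal.tsv"))
  write_tsv(regional, file.path(outdir, "regional.tsv"))
  write_tsv(truth$celltype, file.path(outdir, "truth_celltype.tsv"))
  write_tsv(truth$regulation, file.path(outdir, "truth_regulation.tsv"))
  write_tsv(truth$binding, file.path(outdir, "truth_binding.tsv"))
  cfg_plain <- unclass(config)
  cfg_plain$sim <- unclass(cfg_plain$sim)
  yaml::write_yaml(cfg_plain, file.path(outdir, "config.yaml"))
  invisible(list(gene_models = gm, peaks = pk, expression = expr,
                 truth = truth, zonal = zonal, regional = regional,
                 design = design))
}

# Gene-level mutant DE for every mutant genotype present in the design.
mutant_summaries <- function(matrix, sample_sheet, probe_map, alpha = 0.05,
                             verbose = TRUE) {
  gt_map <- genotype_tf_map()
  out <- list()
  for (gt in intersect(unique(sample_sheet$genotype), names(gt_map))) {
    tf_label <- paste(gt_map[[gt]], collapse = "+")
    exps <- unique(sample_sheet$experiment[sample_sheet$genotype == gt])
    for (ex in exps) {
      has_control <- any(sample_sheet$genotype == "control" &
                           sample_sheet$experiment == ex)
      if (!has_control) next
      pr <- probe_de(matrix, sample_sheet, group_a = gt, group_b = "control",
                     experiment = ex, alpha = alpha, verbose = verbose)
      gs <- gene_de(pr, probe_map, alpha = alpha)
      key <- sprintf("%s|%s", tf_label, ex)
      out[[key]] <- gs
    }
  }
  # merge per-TF across experiments into one summary list named by TF
  tf_names <- sub("\\|.*$", "", names(out))
  merged <- lapply(unique(tf_names), function(tf) {
    parts <- out[tf_names == tf]
    m <- do.call(rbind, parts)
    attr(m, "orientation") <- "a_vs_b"
    m
  })
  names(merged) <- unique(tf_names)
  merged
}

#' Run the complete analysis pipeline on synthetic inputs
#'
#' Orchestrates simulate -> annotate -> differential expression ->
#' cell-type classification -> gradient calling -> regulation calling ->
#' network assembly -> reporting, writing every stage's table under
#' `outdir` together with a run manifest (config hash, seed, row counts).
#' Reruns with an identical config produce byte-identical artifacts.
#'
#' @param config An `ef_config`.
#' @param outdir Artifact directory.
#' @param verbose Emit progress messages.
#' @return Invisibly, a list with all stage results (`binding`, `lineage`,
#'   `celltype`, `gradients`, `regulation`, `network`, `summary`, plus the
#'   simulation objects).
#' @export
run_pipeline <- function(config = default_config(), outdir, verbose = TRUE) {
  validate_config(config)
  sim_objects <- simulate_inputs(config, outdir, verbose = verbose)
  gm <- sim_objects$gene_models
  pk <- sim_objects$peaks
  expr <- sim_objects$expression
  alpha <- config$alpha

  ef_log("calling TF binding", verbose = verbose)
  binding <- call_binding(pk, gm, window_bp = config$window_bp)
  write_tsv(binding, file.path(outdir, "binding.tsv"))

  ef_log("differential expression", verbose = verbose)
  mut <- mutant_summaries(expr$matrix, expr$sample_sheet, expr$probe_map,
                          alpha = alpha, verbose = verbose)
  de <- mutant_de_table(mut)
  write_tsv(de, file.path(outdir, "de_genes.tsv"))
  lineage <- lineage_enrichment(expr$matrix, expr$sample_sheet, expr$probe_map,
                                alpha = alpha, verbose = verbose)
  write_tsv(lineage, file.path(outdir, "lineage.tsv"))

  ef_log("classifying cell types and gradients", verbose = verbose)
  annotations <- data.frame(gene_id = sim_objects$truth$celltype$gene_id,
                            cortex_specific = sim_objects$truth$celltype$cortex_specific,
                            stringsAsFactors = FALSE)
  celltype <- classify_cell_types(lineage, sim_objects$zonal, annotations,
                                  detect_floor = config$detect_floor,
                                  dominance_frac = config$dominance_frac)
  write_tsv(celltype, file.path(outdir, "celltype_calls.tsv"))
  gradients <- classify_gradients(sim_objects$regional,
                                  rho_threshold = config$rho_threshold,
                                  alpha = alpha, n_perm = config$n_perm,
                                  seed = config$seed)
  write_tsv(gradients, file.path(outdir, "gradient_calls.tsv"))

  ef_log("calling regulation", verbose = verbose)
  singles <- call_regulation(binding, de, alpha = alpha)
  synergy <- if ("Tbr1+Tbr2" %in% de$tf) {
    call_synergy(binding, de, tf_pair = "Tbr1+Tbr2", alpha = alpha)
  } else {
    call_regulation_empty()
  }
  regulation <- combine_regulation(singles, synergy)
  write_tsv(regulation, file.path(outdir, "regulation.tsv"))

  ef_log("building network and report", verbose = verbose)
  network <- build_network(regulation)
  export_network(network, file.path(outdir, "network.tsv"), "tsv")
  export_network(network, file.path(outdir, "network.sif"), "sif")
  export_network(network, file.path(outdir, "network.graphml"), "graphml")
  summary <- summarize_network(network, celltype, gradients)
  write_summary(summary, file.path(outdir, "summary.json"),
                file.path(outdir, "summary.md"))

  manifest <- list(
    package = "efcascade",
    version = as.character(utils::packageVersion("efcascade")),
    seed = config$seed,
    config_hash = config_hash(config),
    rows = list(
      binding = nrow(binding), de_genes = nrow(de), lineage = nrow(lineage),
      celltype = nrow(celltype), gradients = nrow(gradients),
      regulation = nrow(regulation), edges = nrow(network$edges)
    )
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(sim_objects, list(binding = binding, de = de, lineage = lineage,
                                celltype = celltype, gradients = gradients,
                                regulation = regulation, network = network,
                                summary = summary)))
}

config_hash <- function(config) {
  cfg_plain <- unclass(config)
  cfg_plain$sim <- unclass(cfg_plain$sim)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg_plain, tmp)
  unname(tools::md5sum(tmp))
}

#' Write a summary report as JSON and Markdown
#'
#' @param summary An `ef_summary` from [summarize_network()].
#' @param json_path,md_path Output paths (either may be NULL to skip).
#' @return Invisibly, NULL.
#' @export
write_summary <- function(summary, json_path = NULL, md_path = NULL) {
  stopifnot(inherits(summary, "ef_summary"))
  if (!is.null(json_path)) {
    jsonlite::write_json(unclass(summary), json_path, auto_unbox = TRUE,
                         pretty = TRUE, dataframe = "rows")
  }
  if (!is.null(md_path)) {
    lines <- c(
      "# Regulation summary", "",
      "## Direct regulation by TF", "",
      "| TF | activated | repressed | synergistic |",
      "|----|-----------|-----------|-------------|",
      sprintf("| %s | %d | %d | %d |", summary$per_tf$tf,
              summary$per_tf$activated, summary$per_tf$repressed,
              summary$per_tf$synergistic)
    )
    if (!is.null(summary$celltype_counts)) {
      nz <- summary$celltype_counts[summary$celltype_counts$n_genes > 0, ]
      lines <- c(lines, "", "## Cell-type labels", "",
                 sprintf("- %s: %d", nz$label, nz$n_genes))
    }
    if (!is.null(summary$gradient_counts)) {
      lines <- c(lines, "", "## Rostrocaudal gradients", "",
                 sprintf("- %s: %d", summary$gradient_counts$direction,
                         summary$gradient_counts$n_genes))
    }
    lines <- c(lines, "",
               sprintf("Union of specific, graded, or regulated genes: %d",
                       summary$n_union))
    writeLines(lines, md_path)
  }
  invisible(NULL)
}

#' Validate pipeline input files in a directory
#'
#' Checks existence, column schemas, and id cross-consistency of the
#' standard input files (`genes.bed`, `expression.tsv`, `samples.tsv`,
#' `probe_map.tsv`, `zonal.tsv`, `regional.tsv`).
#'
#' @param indir Directory holding the input files.
#' @return Data frame of violations (`file`, `rule`, `message`); zero rows
#'   when the inputs are clean.
#' @export
validate_inputs <- function(indir) {
  issues <- list()
  add <- function(file, rule, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      file = file, rule = rule, message = message, stringsAsFactors = FALSE
    )
  }
  need <- c("genes.bed", "expression.tsv", "samples.tsv", "probe_map.tsv",
            "zonal.tsv", "regional.tsv")
  for (f in need) {
    if (!file.exists(file.path(indir, f))) add(f, "exists", "file is missing")
  }
  done <- function() {
    out <- do.call(rbind, issues)
    if (is.null(out)) {
      out <- data.frame(file = character(), rule = character(),
                        message = character(), stringsAsFactors = FALSE)
    }
    out
  }
  if (nrow(done())) return(done())

  gm <- tryCatch(read_gene_models(file.path(indir, "genes.bed")),
                 error = function(e) {
                   add("genes.bed", "schema", conditionMessage(e)); NULL
                 })
  samples <- read_tsv(file.path(indir, "samples.tsv"))
  for (col in c("sample_id", "genotype", "experiment", "lineage_fraction")) {
    if (!col %in% names(samples)) {
      add("samples.tsv", "schema", paste0("missing column: ", col))
    }
  }
  pm <- read_tsv(file.path(indir, "probe_map.tsv"))
  for (col in c("probe_id", "gene_id")) {
    if (!col %in% names(pm)) add("probe_map.tsv", "schema",
                                 paste0("missing column: ", col))
  }
  if (!is.null(gm) && all(c("probe_id", "gene_id") %in% names(pm))) {
    unknown <- setdiff(pm$gene_id, gm$gene_id)
    if (length(unknown)) {
      add("probe_map.tsv", "cross_reference",
          paste0("probe map references unknown gene(s): ",
                 paste(head(unknown, 5), collapse = ", ")))
    }
  }
  mat <- read_expression_matrix(file.path(indir, "expression.tsv"))
  if ("sample_id" %in% names(samples)) {
    unknown <- setdiff(colnames(mat), samples$sample_id)
    if (length(unknown)) {
      add("expression.tsv", "cross_reference",
          paste0("matrix columns absent from sample sheet: ",
                 paste(head(unknown, 5), collapse = ", ")))
    }
  }
  if ("probe_id" %in% names(pm)) {
    unknown <- setdiff(rownames(mat), pm$probe_id)
    if (length(unknown)) {
      add("expression.tsv", "cross_reference",
          paste0("matrix probes absent from probe map: ",
                 paste(head(unknown, 5), collapse = ", ")))
    }
  }
  zonal <- read_tsv(file.path(indir, "zonal.tsv"))
  if (!identical(intersect(names(zonal), CORTICAL_ZONES), CORTICAL_ZONES)) {
    add("zonal.tsv", "schema",
        "zone columns must be VZ, SVZ, IZ, CP in apical-to-pial order")
  }
  regional <- read_tsv(file.path(indir, "regional.tsv"))
  bins <- grep("^bin_", names(regional), value = TRUE)
  if (length(bins) < 3L) {
    add("regional.tsv", "schema", "need >= 3 ordered bin_* columns")
  } else {
    idx <- as.integer(sub("bin_", "", bins))
    if (any(is.na(idx)) || !identical(idx, seq_along(idx))) {
      add("regional.tsv", "schema", "bin_* columns must be bin_1..bin_n in order")
    }
  }
  done()
}
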