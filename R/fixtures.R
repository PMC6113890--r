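#' Curated TF-trio cascade fixture
#'
#' Encodes the published binding and expression relationships among Pax6,
#' Tbr2 (Eomes), and Tbr1 in E14.5 mouse neocortex as a ready-to-analyse
#' fixture: ChIP-seq binding of Pax6 at the *Pax6* and *Tbr2* loci, Tbr2 at
#' *Pax6*, *Tbr2*, and *Tbr1*, and Tbr1 at *Tbr2* only; microarray
#' log2 fold changes of *Pax6* (+1.20, p = 1e-6) and *Tbr2* (-1.07,
#' p = 1e-6) in Pax6-null cortex, *Pax6* upregulation in Tbr2-cKO cortex
#' (+0.36, p = 1e-3 on MA1; +0.49, p = 1e-3 on MA2), *Tbr1* downregulation
#' in Tbr2-cKO cortex, and the non-significant *Tbr2* change in Tbr1-null
#' cortex. *Tbr1* and the Tbr2-cKO values without published magnitudes use
#' synthetic stand-in effect sizes with the published direction and
#' significance. The *Tbr2* transcript in Tbr2-cKO cortex is on the
#' exclusion list (its reduction is an artifact of the conditional allele).
#'
#' @return List with `binding_calls`, `de` (a [mutant_de_table()]-style
#'   table), `exclusions`, and `tf_order`.
#' @export
cascade_fixture <- function() {
  genes <- c("Pax6", "Tbr2", "Tbr1")
  bind <- function(tf, bound_genes) {
    data.frame(
      gene_id = genes, tf = tf, bound = genes %in% bound_genes,
      min_gap_bp = ifelse(genes %in% bound_genes, 0, NA_real_),
      supporting_peak_ids = ifelse(genes %in% bound_genes,
                                   paste0(tf, "_pk_", genes), ""),
      stringsAsFactors = FALSE
    )
  }
  binding <- rbind(
    bind("Pax6", c("Pax6", "Tbr2")),
    bind("Tbr2", c("Pax6", "Tbr2", "Tbr1")),
    bind("Tbr1", "Tbr2")
  )
  de <- data.frame(
    tf = c("Pax6", "Pax6",
           "Tbr2", "Tbr2", "Tbr2", "Tbr2", "Tbr2",
           "Tbr1", "Tbr1"),
    gene_id = c("Pax6", "Tbr2",
                "Pax6", "Pax6", "Tbr1", "Tbr1", "Tbr2",
                "Tbr2", "Tbr2"),
    experiment = c("P1", "P1",
                   "MA1", "MA2", "MA1", "MA2", "MA2",
                   "MA1", "MA2"),
    log2fc = c(1.20, -1.07,
               0.36, 0.49, -0.62, -0.55, -1.80,
               0.05, -0.08),
    p_value = c(1e-6, 1e-6,
                1e-3, 1e-3, 0.01, 0.02, 1e-4,
                0.45, 0.60),
    stringsAsFactors = FALSE
  )
  de$significant <- de$p_value < 0.05
  attr(de, "orientation") <- "mutant_vs_control"
  exclusions <- data.frame(tf = "Tbr2", gene_id = "Tbr2",
                           stringsAsFactors = FALSE)
  list(binding_calls = binding, de = de, exclusions = exclusions,
       tf_order = c("Pax6", "Tbr2", "Tbr1"))
}

#' Curated epigenetic-factor call fixture
#'
#' Published gene-level statements assembled into inputs for the regulation
#' and classification callers, with the qualitative call expected for each
#' row: Tbr2 represses *Hdac9* (+0.55, p = 2e-4 on MA1; +0.68, p = 0.008 on
#' MA2); Tbr1 activates *Rybp* and *Auts2* (stand-in magnitudes, published
#' direction); Tbr1 and Tbr2 synergistically activate *Chd3* (significant
#' only in the double mutant); *Kdm5a* has conflicted lineage probes;
#' *Bcl7c* (Baf40c) is GFP-minus-enriched (log2FC = -1.07) and expressed in
#' VZ, defining an RGP gene; *Rcor2* is GFP-plus-enriched (log2FC = +1.94)
#' with bilaminar VZ+SVZ expression, defining an aIP+bIP gene.
#'
#' @return List with `binding_calls`, `de`, `lineage_probes` (probe-level
#'   lineage results), `probe_map`, `zonal`, and `expected` (data frame of
#'   gene, expected call).
#' @export
ef_call_fixture <- function() {
  genes <- c("Hdac9", "Rybp", "Auts2", "Chd3", "Kdm5a", "Bcl7c", "Rcor2")
  bind1 <- function(tf, bound_genes) {
    data.frame(
      gene_id = genes, tf = tf, bound = genes %in% bound_genes,
      min_gap_bp = ifelse(genes %in% bound_genes, 0, NA_real_),
      supporting_peak_ids = ifelse(genes %in% bound_genes,
                                   paste0(tf, "_pk_", genes), ""),
      stringsAsFactors = FALSE
    )
  }
  binding <- rbind(
    bind1("Tbr2", c("Hdac9", "Chd3")),
    bind1("Tbr1", c("Rybp", "Auts2", "Chd3"))
  )
  de <- data.frame(
    tf = c("Tbr2", "Tbr2",
           "Tbr1", "Tbr1",
           "Tbr1", "Tbr1", "Tbr2", "Tbr2",
           "Tbr1+Tbr2"),
    gene_id = c("Hdac9", "Hdac9",
                "Rybp", "Auts2",
                "Chd3", "Chd3", "Chd3", "Chd3",
                "Chd3"),
    experiment = c("MA1", "MA2",
                   "MA1", "MA1",
                   "MA1", "MA2", "MA1", "MA2",
                   "MA2"),
    log2fc = c(0.55, 0.68,
               -0.52, -0.48,
               -0.10, -0.05, -0.12, -0.08,
               -0.80),
    p_value = c(2e-4, 0.008,
                0.01, 0.02,
                0.35, 0.60, 0.40, 0.55,
                0.01),
    stringsAsFactors = FALSE
  )
  de$significant <- de$p_value < 0.05
  attr(de, "orientation") <- "mutant_vs_control"

  # probe-level lineage enrichment (Tbr2-GFP+ vs GFP-)
  lineage_probes <- data.frame(
    probe_id = c("Kdm5a_p1", "Kdm5a_p2", "Bcl7c_p1", "Rcor2_p1"),
    group_a = "GFP_pos", group_b = "GFP_neg", experiment = "LIN",
    n_a = 4L, n_b = 4L,
    log2fc = c(0.90, -0.70, -1.07, 1.94),
    t = NA_real_, df = NA_real_,
    p_value = c(0.01, 0.02, 1e-4, 1e-5),
    method = "welch",
    stringsAsFactors = FALSE
  )
  lineage_probes$significant <- lineage_probes$p_value < 0.05
  attr(lineage_probes, "orientation") <- "a_vs_b"
  probe_map <- data.frame(
    probe_id = lineage_probes$probe_id,
    gene_id = sub("_p[0-9]+$", "", lineage_probes$probe_id),
    stringsAsFactors = FALSE
  )
  zonal <- data.frame(
    gene_id = c("Kdm5a", "Bcl7c", "Rcor2"),
    VZ = c(2.0, 3.0, 2.8),
    SVZ = c(2.0, 0.1, 2.5),
    IZ = c(0.1, 0.1, 0.1),
    CP = c(0.1, 0.1, 0.1),
    stringsAsFactors = FALSE
  )
  expected <- data.frame(
    gene_id = genes,
    expected = c("Tbr2 represses", "Tbr1 activates", "Tbr1 activates",
                 "Tbr1+Tbr2 synergistic_activates", "conflicted",
                 "RGP", "aIP+bIP"),
    stringsAsFactors = FALSE
  )
  list(binding_calls = binding, de = de, lineage_probes = lineage_probes,
       probe_map = probe_map, zonal = zonal, expected = expected)
}
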