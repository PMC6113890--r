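# Vectorised two-sample t-tests across matrix rows.
#
# Handles the degenerate cases that arise with planted zero-noise data:
# zero pooled variance with a nonzero mean difference gives p = 0 (infinite
# t), zero variance with zero difference gives p = 1 (no evidence).
row_ttest <- function(mat_a, mat_b, method = c("auto", "welch", "pooled"),
                      verbose = TRUE) {
  method <- match.arg(method)
  na <- ncol(mat_a)
  nb <- ncol(mat_b)
  if (na < 1L || nb < 1L) stop_ef("both groups must be non-empty")
  used <- method
  if (method == "auto") {
    used <- if (min(na, nb) < 3L) "pooled" else "welch"
    if (used == "pooled") {
      ef_log("group size < 3: using pooled-variance Student's t instead of Welch",
             verbose = verbose)
    }
  }
  if (used == "welch" && min(na, nb) < 2L) {
    used <- "pooled"
    ef_log("group with < 2 samples: falling back to pooled-variance Student's t",
           verbose = verbose)
  }
  ma <- rowMeans(mat_a)
  mb <- rowMeans(mat_b)
  va <- if (na > 1L) apply(mat_a, 1L, stats::var) else rep(NA_real_, nrow(mat_a))
  vb <- if (nb > 1L) apply(mat_b, 1L, stats::var) else rep(NA_real_, nrow(mat_b))
  diff <- ma - mb
  if (used == "welch") {
    sea2 <- va / na
    seb2 <- vb / nb
    se <- sqrt(sea2 + seb2)
    df <- (sea2 + seb2)^2 / (sea2^2 / (na - 1) + seb2^2 / (nb - 1))
  } else {
    df <- rep(na + nb - 2, length(diff))
    ssa <- ifelse(is.na(va), 0, (na - 1) * va)
    ssb <- ifelse(is.na(vb), 0, (nb - 1) * vb)
    sp2 <- (ssa + ssb) / df
    se <- sqrt(sp2 * (1 / na + 1 / nb))
  }
  tt <- diff / se
  p <- 2 * pt(-abs(tt), df)
  zero_se <- is.finite(se) & se == 0
  p[zero_se & diff != 0] <- 0
  p[zero_se & diff == 0] <- 1
  tt[zero_se & diff == 0] <- 0
  undef <- (!is.na(df) & df < 1) | is.na(se)
  p[undef] <- NA_real_
  data.frame(log2fc = diff, t = tt, df = df, p_value = p,
             method = used, stringsAsFactors = FALSE)
}

select_samples <- function(sample_sheet, genotype = NULL, fraction = NULL,
                           experiment = NULL) {
  keep <- rep(TRUE, nrow(sample_sheet))
  if (!is.null(genotype)) keep <- keep & sample_sheet$genotype == genotype
  if (!is.null(fraction)) keep <- keep & sample_sheet$lineage_fraction == fraction
  if (!is.null(experiment)) keep <- keep & sample_sheet$experiment == experiment
  sample_sheet$sample_id[keep]
}

#' Probe-level differential expression between two genotypes
#'
#' Computes per-probe log2 fold change (mean of `group_a` minus mean of
#' `group_b`) and a two-sample t-test p-value within one experiment. The
#' default statistic is Welch's t-test; when either group has fewer than 3
#' samples the test automatically falls back to the pooled-variance
#' Student's t (and logs the switch). For mutant contrasts `group_a` should
#' be the mutant genotype and `group_b` the control, so positive log2FC
#' means derepression in the mutant.
#'
#' @param matrix Probe x sample log2 expression matrix.
#' @param sample_sheet Sample sheet with `sample_id`, `genotype`,
#'   `experiment`, `lineage_fraction` columns.
#' @param group_a,group_b Genotype labels of the contrast (a vs b).
#' @param experiment Experiment id the contrast is computed within.
#' @param alpha Significance level (strict inequality, p < alpha).
#' @param method `"auto"` (default), `"welch"`, or `"pooled"`.
#' @param verbose Emit log messages.
#' @return Data frame, one row per probe, with columns `probe_id`,
#'   `group_a`, `group_b`, `experiment`, `n_a`, `n_b`, `log2fc`, `t`, `df`,
#'   `p_value`, `p_adj` (Benjamini-Hochberg, informational), `significant`,
#'   `method`. Carries attribute `orientation = "a_vs_b"`.
#' @export
probe_de <- function(matrix, sample_sheet, group_a, group_b, experiment,
                     alpha = 0.05, method = "auto", verbose = TRUE) {
  if (alpha <= 0 || alpha >= 1) stop_ef("alpha must be in (0, 1)")
  sa <- select_samples(sample_sheet, genotype = group_a, experiment = experiment)
  sa <- sa[sample_sheet$lineage_fraction[match(sa, sample_sheet$sample_id)] == "bulk"]
  sb <- select_samples(sample_sheet, genotype = group_b, experiment = experiment)
  sb <- sb[sample_sheet$lineage_fraction[match(sb, sample_sheet$sample_id)] == "bulk"]
  if (!length(sa)) stop_ef("no samples for genotype ", group_a,
                           " in experiment ", experiment)
  if (!length(sb)) stop_ef("no samples for genotype ", group_b,
                           " in experiment ", experiment)
  if (length(intersect(sa, sb))) stop_ef("contrast groups overlap")
  res <- row_ttest(matrix[, sa, drop = FALSE], matrix[, sb, drop = FALSE],
                   method = method, verbose = verbose)
  out <- data.frame(
    probe_id = rownames(matrix),
    group_a = group_a, group_b = group_b, experiment = experiment,
    n_a = length(sa), n_b = length(sb),
    res,
    stringsAsFactors = FALSE
  )
  out$p_adj <- p.adjust(out$p_value, method = "BH")
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  attr(out, "orientation") <- "a_vs_b"
  rownames(out) <- NULL
  out
}

#' Aggregate probe-level results to gene level
#'
#' The probe with the smallest p-value represents the gene (ties broken by
#' larger absolute log2FC, then probe id). A gene is `conflicted` when at
#' least two of its probes are individually significant with opposite
#' log2FC signs; conflicted genes get direction `none` for classification
#' purposes. Probes without a mapping are excluded with a warning.
#'
#' @param probe_results Output of [probe_de()] or [lineage_enrichment()]
#'   at probe level.
#' @param probe_map Data frame with `probe_id`, `gene_id`.
#' @param alpha Significance level (p < alpha).
#' @return Data frame with one row per gene: `gene_id`, `group_a`,
#'   `group_b`, `experiment`, `n_probes`, `best_probe`, `best_log2fc`,
#'   `best_p`, `significant`, `direction` (`up`/`down`/`none`),
#'   `conflicted`.
#' @export
gene_de <- function(probe_results, probe_map, alpha = 0.05) {
  idx <- match(probe_results$probe_id, probe_map$probe_id)
  unmapped <- is.na(idx)
  if (any(unmapped)) {
    warning(sum(unmapped), " probe(s) without gene mapping excluded",
            call. = FALSE)
    probe_results <- probe_results[!unmapped, , drop = FALSE]
    idx <- idx[!unmapped]
  }
  if (anyDuplicated(probe_map$probe_id) > 0L) {
    stop_ef("every probe must map to exactly one gene")
  }
  probe_results$gene_id <- probe_map$gene_id[idx]
  sp <- split(probe_results, probe_results$gene_id)
  rows <- lapply(sp, function(d) {
    ord <- order(d$p_value, -abs(d$log2fc), d$probe_id, na.last = TRUE)
    best <- d[ord[1L], ]
    sig <- !is.na(d$p_value) & d$p_value < alpha
    conflicted <- any(sig & d$log2fc > 0) && any(sig & d$log2fc < 0)
    significant <- !is.na(best$p_value) && best$p_value < alpha
    direction <- if (!significant || conflicted) {
      "none"
    } else if (best$log2fc > 0) "up" else "down"
    data.frame(
      gene_id = best$gene_id,
      group_a = best$group_a, group_b = best$group_b,
      experiment = best$experiment,
      n_probes = nrow(d),
      best_probe = best$probe_id,
      best_log2fc = best$log2fc,
      best_p = best$p_value,
      significant = significant,
      direction = direction,
      conflicted = conflicted,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "orientation") <- attr(probe_results, "orientation") %||% "a_vs_b"
  out
}

#' Gene-level lineage enrichment (Tbr2-GFP+ vs GFP-)
#'
#' Contrasts the GFP+ against the GFP- sorted fraction: positive log2FC
#' means enrichment in the GFP+ (IP/neuron) lineage, negative log2FC
#' enrichment in the GFP- (RGP and non-PN) fraction.
#'
#' @param matrix Probe x sample log2 expression matrix.
#' @param sample_sheet Sample sheet.
#' @param probe_map Probe-to-gene map.
#' @param alpha Significance level.
#' @param method Test statistic passed to [probe_de()] machinery.
#' @param verbose Emit log messages.
#' @return Gene-level summary as from [gene_de()], with
#'   `group_a = "GFP_pos"`, `group_b = "GFP_neg"`.
#' @export
lineage_enrichment <- function(matrix, sample_sheet, probe_map, alpha = 0.05,
                               method = "auto", verbose = TRUE) {
  sa <- select_samples(sample_sheet, fraction = "GFP_pos")
  sb <- select_samples(sample_sheet, fraction = "GFP_neg")
  if (!length(sa) || !length(sb)) {
    stop_ef("both lineage fractions (GFP_pos, GFP_neg) must be present")
  }
  exp_id <- unique(sample_sheet$experiment[sample_sheet$sample_id %in% c(sa, sb)])
  res <- row_ttest(matrix[, sa, drop = FALSE], matrix[, sb, drop = FALSE],
                   method = method, verbose = verbose)
  pr <- data.frame(
    probe_id = rownames(matrix),
    group_a = "GFP_pos", group_b = "GFP_neg",
    experiment = paste(exp_id, collapse = "+"),
    n_a = length(sa), n_b = length(sb),
    res, stringsAsFactors = FALSE
  )
  pr$significant <- !is.na(pr$p_value) & pr$p_value < alpha
  attr(pr, "orientation") <- "a_vs_b"
  gene_de(pr, probe_map, alpha = alpha)
}
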