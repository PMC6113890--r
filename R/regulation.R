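#' Build a mutant DE summary table for regulation calling
#'
#' Stacks gene-level summaries from mutant-vs-control contrasts and records
#' which TF each contrast interrogates. All contrasts must be oriented
#' mutant (group_a) versus control (group_b); the orientation attribute set
#' by [probe_de()]/[gene_de()] is required, because the sign semantics of
#' regulation calls depend on it.
#'
#' @param summaries Named list of gene-level summaries (from [gene_de()]);
#'   names are the TF (or TF pair, e.g. `"Tbr1+Tbr2"`) disrupted in the
#'   mutant of each contrast.
#' @return Data frame with columns `tf`, `gene_id`, `experiment`, `log2fc`,
#'   `p_value`, `significant`, carrying `orientation = "mutant_vs_control"`.
#' @export
mutant_de_table <- function(summaries) {
  if (is.null(names(summaries)) || any(!nzchar(names(summaries)))) {
    stop_ef("summaries must be a named list (names = disrupted TF)")
  }
  rows <- lapply(names(summaries), function(tf) {
    s <- summaries[[tf]]
    if (is.null(attr(s, "orientation"))) {
      stop_ef("contrast orientation metadata missing for ", tf,
              "; sign semantics undefined")
    }
    data.frame(
      tf = tf, gene_id = s$gene_id, experiment = s$experiment,
      log2fc = s$best_log2fc, p_value = s$best_p,
      significant = s$significant, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "orientation") <- "mutant_vs_control"
  out
}

#' Call direct single-TF regulation from binding and mutant expression
#'
#' Implements the intersectional direct-target rule: a gene is a direct
#' target of a TF when it is bound (peak in the gene body or within the
#' binding window) *and* differentially expressed (p < alpha) in that TF's
#' mutant on *any* experiment. The direction follows loss-of-function
#' logic on the mutant-vs-control contrast: log2FC > 0 in the mutant means
#' the TF normally represses the gene; log2FC < 0 means the TF activates
#' it. Bound genes never reaching significance are `bound_no_de`; unbound
#' genes are `not_bound` regardless of expression. Genes on the exclusion
#' list (expression changes that are artifacts of the mutant design, e.g. a
#' conditional allele's own transcript) are reported `bound_no_de` with a
#' note. When several experiments are significant with conflicting signs,
#' the smaller p-value sets the mode and a conflict flag is raised.
#'
#' @param binding_calls Output of [call_binding()].
#' @param de Mutant DE table from [mutant_de_table()] (orientation
#'   mutant-vs-control required).
#' @param exclusions Optional data frame with `tf`, `gene_id` pairs to
#'   exclude.
#' @param alpha Significance level (p < alpha).
#' @return Data frame with one row per (tf, gene): `tf`, `gene_id`, `mode`,
#'   `log2fc`, `p_value`, `experiment` (of the representative contrast),
#'   `experiments_used`, `sign_conflict`, `note`.
#' @export
call_regulation <- function(binding_calls, de, exclusions = NULL, alpha = 0.05) {
  if (!identical(attr(de, "orientation"), "mutant_vs_control")) {
    stop_ef("DE table must carry orientation 'mutant_vs_control' ",
            "(build it with mutant_de_table())")
  }
  tfs <- sort(unique(binding_calls$tf))
  de_tfs <- unique(de$tf)
  single_de_tfs <- de_tfs[!grepl("+", de_tfs, fixed = TRUE)]
  no_de <- setdiff(tfs, single_de_tfs)
  if (length(no_de)) {
    stop_ef("no mutant contrast available for TF(s): ",
            paste(no_de, collapse = ", "))
  }
  excl_key <- if (!is.null(exclusions) && nrow(exclusions)) {
    paste(exclusions$tf, exclusions$gene_id)
  } else {
    character(0)
  }
  rows <- list()
  for (tf in tfs) {
    b <- binding_calls[binding_calls$tf == tf, , drop = FALSE]
    d <- de[de$tf == tf, , drop = FALSE]
    exps <- sort(unique(d$experiment))
    for (i in seq_len(nrow(b))) {
      gene <- b$gene_id[i]
      dg <- d[d$gene_id == gene, , drop = FALSE]
      sig <- dg[!is.na(dg$p_value) & dg$p_value < alpha, , drop = FALSE]
      note <- ""
      conflict <- FALSE
      if (!b$bound[i]) {
        mode <- "not_bound"
        lfc <- NA_real_; p <- NA_real_; ex <- NA_character_
      } else if (paste(tf, gene) %in% excl_key) {
        mode <- "bound_no_de"
        note <- "excluded: expression change is an artifact of the mutant design"
        lfc <- NA_real_; p <- NA_real_; ex <- NA_character_
      } else if (nrow(sig) == 0L) {
        mode <- "bound_no_de"
        best <- if (nrow(dg)) which.min(dg$p_value) else integer(0)
        lfc <- if (length(best)) dg$log2fc[best] else NA_real_
        p <- if (length(best)) dg$p_value[best] else NA_real_
        ex <- if (length(best)) dg$experiment[best] else NA_character_
      } else {
        if (length(unique(sign(sig$log2fc))) > 1L) {
          conflict <- TRUE
          note <- "significant experiments disagree in sign; smaller p wins"
        }
        best <- which.min(sig$p_value)
        lfc <- sig$log2fc[best]
        p <- sig$p_value[best]
        ex <- sig$experiment[best]
        mode <- if (lfc > 0) "represses" else "activates"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        tf = tf, gene_id = gene, mode = mode,
        log2fc = lfc, p_value = p, experiment = ex,
        experiments_used = paste(exps, collapse = ","),
        sign_conflict = conflict, note = note,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Call Tbr1/Tbr2 synergistic regulation
#'
#' A gene is regulated synergistically by a TF pair when it is bound by
#' *both* TFs, significantly differentially expressed in the double mutant
#' (on any experiment covering it), and *not* significant in either single
#' mutant on any experiment. The direction comes from the double-mutant
#' sign: down in the double mutant means the pair synergistically activates
#' the gene. Genes bound by both TFs that fail the expression conditions
#' are reported `bound_no_de` with the failing condition in `note`.
#'
#' @param binding_calls Output of [call_binding()].
#' @param de Mutant DE table from [mutant_de_table()], containing both
#'   single-mutant TFs and the pair (e.g. `"Tbr1+Tbr2"`).
#' @param tf_pair The pair label, matching a `tf` value in `de`.
#' @param alpha Significance level.
#' @return Data frame with one row per double-bound gene, columns as in
#'   [call_regulation()] (modes `synergistic_activates`,
#'   `synergistic_represses`, or `bound_no_de`).
#' @export
call_synergy <- function(binding_calls, de, tf_pair = "Tbr1+Tbr2", alpha = 0.05) {
  if (!identical(attr(de, "orientation"), "mutant_vs_control")) {
    stop_ef("DE table must carry orientation 'mutant_vs_control'")
  }
  tfs <- strsplit(tf_pair, "+", fixed = TRUE)[[1]]
  if (length(tfs) != 2L) stop_ef("tf_pair must name two TFs, e.g. 'Tbr1+Tbr2'")
  dd <- de[de$tf == tf_pair, , drop = FALSE]
  if (nrow(dd) == 0L) stop_ef("missing double-mutant contrast for ", tf_pair)
  missing_single <- setdiff(tfs, unique(de$tf))
  if (length(missing_single)) {
    stop_ef("missing single-mutant contrast(s): ",
            paste(missing_single, collapse = ", "))
  }
  b1 <- binding_calls$gene_id[binding_calls$tf == tfs[1] & binding_calls$bound]
  b2 <- binding_calls$gene_id[binding_calls$tf == tfs[2] & binding_calls$bound]
  both <- sort(intersect(b1, b2))
  sig_of <- function(tf, gene) {
    d <- de[de$tf == tf & de$gene_id == gene, , drop = FALSE]
    d[!is.na(d$p_value) & d$p_value < alpha, , drop = FALSE]
  }
  rows <- lapply(both, function(gene) {
    sd1 <- nrow(sig_of(tfs[1], gene)) > 0L
    sd2 <- nrow(sig_of(tfs[2], gene)) > 0L
    sdd <- sig_of(tf_pair, gene)
    note <- ""
    if (nrow(sdd) && !sd1 && !sd2) {
      best <- which.min(sdd$p_value)
      lfc <- sdd$log2fc[best]
      mode <- if (lfc < 0) "synergistic_activates" else "synergistic_represses"
      p <- sdd$p_value[best]
      ex <- sdd$experiment[best]
    } else {
      mode <- "bound_no_de"
      note <- if (sd1 || sd2) {
        "significant in a single mutant; assigned by single-TF regulation"
      } else {
        "no significant double-mutant differential expression"
      }
      lfc <- NA_real_; p <- NA_real_; ex <- NA_character_
    }
    data.frame(
      tf = tf_pair, gene_id = gene, mode = mode,
      log2fc = lfc, p_value = p, experiment = ex,
      experiments_used = paste(sort(unique(dd$experiment)), collapse = ","),
      sign_conflict = FALSE, note = note, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- call_regulation_empty()
  }
  rownames(out) <- NULL
  out
}

call_regulation_empty <- function() {
  data.frame(
    tf = character(), gene_id = character(), mode = character(),
    log2fc = numeric(), p_value = numeric(), experiment = character(),
    experiments_used = character(), sign_conflict = logical(),
    note = character(), stringsAsFactors = FALSE
  )
}

#' Combine single-TF and synergy calls into one table
#'
#' Stacks the two call sets and checks the exclusivity invariant: a gene
#' carrying a synergy edge must not also carry a single-TF edge for either
#' member of the pair (the synergy rule itself guarantees this when both
#' tables come from the same DE input).
#'
#' @param single_calls Output of [call_regulation()].
#' @param synergy_calls Output of [call_synergy()].
#' @return Row-bound call table.
#' @export
combine_regulation <- function(single_calls, synergy_calls) {
  edge_modes <- c("activates", "represses")
  syn <- synergy_calls[startsWith(synergy_calls$mode, "synergistic"), , drop = FALSE]
  for (i in seq_len(nrow(syn))) {
    tfs <- strsplit(syn$tf[i], "+", fixed = TRUE)[[1]]
    clash <- single_calls$gene_id == syn$gene_id[i] &
      single_calls$tf %in% tfs & single_calls$mode %in% edge_modes
    if (any(clash)) {
      stop_ef("gene ", syn$gene_id[i], " carries both a synergy edge and a ",
              "single-TF edge for an overlapping TF")
    }
  }
  out <- rbind(single_calls, synergy_calls)
  rownames(out) <- NULL
  out
}
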