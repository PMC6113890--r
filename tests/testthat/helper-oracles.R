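# Independent brute-force oracles and small fixture builders.
# These deliberately avoid the package's fast code paths: gaps by per-base
# scans or scalar arithmetic, binding by O(n*m) pair loops, motifs by
# subsequence enumeration, gene summaries by direct rule evaluation.

# Gap via a literal per-base scan (0-based half-open): count integer
# positions occupied by neither interval and lying strictly between them.
# Only usable for small coordinates.
scan_gap <- function(s1, e1, s2, e2) {
  occ1 <- seq(s1, e1 - 1)
  occ2 <- seq(s2, e2 - 1)
  if (length(intersect(occ1, occ2))) return(0)
  lo <- min(max(occ1), max(occ2))
  hi <- max(min(occ1), min(occ2))
  if (hi - lo < 2) return(0)
  cand <- (lo + 1):(hi - 1)
  sum(!(cand %in% c(occ1, occ2)))
}

# Scalar interval gap, written independently of peak_gene_gap().
pair_gap <- function(s1, e1, s2, e2) {
  if (e1 <= s2) s2 - e1 else if (e2 <= s1) s1 - e2 else 0
}

# O(n*m) binding oracle: every same-chromosome (gene, peak) pair of each
# TF is scored with the plain edge-to-edge arithmetic (vectorised over
# peaks; no interval index is involved).
brute_binding <- function(peaks, genes, window_bp) {
  # the documented rule ignores peaks on chromosomes absent from the gene set
  peaks <- peaks[peaks$chrom %in% genes$chrom, , drop = FALSE]
  out <- vector("list", 0L)
  for (tf in sort(unique(peaks$tf))) {
    pk <- peaks[peaks$tf == tf, , drop = FALSE]
    rows <- lapply(seq_len(nrow(genes)), function(i) {
      same <- pk$chrom == genes$chrom[i]
      gaps <- pmax(0, pmax(genes$start[i] - pk$end[same],
                           pk$start[same] - genes$end[i]))
      ids <- pk$peak_id[same]
      mg <- if (length(gaps)) min(gaps) else NA_real_
      sup <- if (length(gaps)) sort(ids[gaps <= window_bp]) else character(0)
      data.frame(
        gene_id = genes$gene_id[i], tf = tf,
        bound = !is.na(mg) && mg <= window_bp,
        min_gap_bp = mg,
        supporting_peak_ids = paste(sup, collapse = ","),
        stringsAsFactors = FALSE
      )
    })
    out <- c(out, rows)
  }
  do.call(rbind, out)
}

# Exhaustive closest-gene scan with the documented tie-break.
brute_annotate <- function(peaks, genes, window_bp) {
  gene_id <- rep(NA_character_, nrow(peaks))
  gap_bp <- rep(NA_real_, nrow(peaks))
  for (j in seq_len(nrow(peaks))) {
    cand <- genes[genes$chrom == peaks$chrom[j], , drop = FALSE]
    if (nrow(cand) == 0L) next
    gaps <- pmax(0, pmax(cand$start - peaks$end[j], peaks$start[j] - cand$end))
    ord <- order(gaps, cand$start, cand$gene_id)
    if (gaps[ord[1]] <= window_bp) {
      gene_id[j] <- cand$gene_id[ord[1]]
      gap_bp[j] <- gaps[ord[1]]
    }
  }
  data.frame(peak_id = peaks$peak_id, gene_id = gene_id, gap_bp = gap_bp,
             stringsAsFactors = FALSE)
}

# Random gene/peak instance on a small coordinate space.
random_genome <- function(n_genes, n_peaks, n_chroms = 2, span = 2000,
                          max_len = 60, tfs = c("TFa", "TFb")) {
  g_start <- sample.int(span, n_genes, replace = TRUE) - 1L
  g_len <- sample.int(max_len, n_genes, replace = TRUE)
  genes <- data.frame(
    gene_id = sprintf("g%03d", seq_len(n_genes)),
    symbol = sprintf("g%03d", seq_len(n_genes)),
    chrom = paste0("chr", sample.int(n_chroms, n_genes, replace = TRUE)),
    start = g_start, end = g_start + g_len,
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    stringsAsFactors = FALSE
  )
  genes <- genes[order(genes$chrom, genes$start), ]
  rownames(genes) <- NULL
  p_start <- sample.int(span, n_peaks, replace = TRUE) - 1L
  p_len <- sample.int(max_len, n_peaks, replace = TRUE)
  peaks <- data.frame(
    peak_id = sprintf("p%03d", seq_len(n_peaks)),
    tf = sample(tfs, n_peaks, replace = TRUE),
    chrom = paste0("chr", sample.int(n_chroms, n_peaks, replace = TRUE)),
    start = p_start, end = p_start + p_len,
    score = 1,
    stringsAsFactors = FALSE
  )
  list(genes = genes, peaks = peaks)
}

# Direct evaluation of the gene-aggregation rule.
brute_gene_summary <- function(probes, alpha = 0.05) {
  sp <- split(probes, probes$gene_id)
  rows <- lapply(sp, function(d) {
    sig <- d$p_value < alpha
    conflicted <- any(sig & d$log2fc > 0) && any(sig & d$log2fc < 0)
    best <- which(d$p_value == min(d$p_value))
    if (length(best) > 1L) {
      best <- best[order(-abs(d$log2fc[best]), d$probe_id[best])][1]
    }
    significant <- d$p_value[best] < alpha
    direction <- if (!significant || conflicted) "none" else
      if (d$log2fc[best] > 0) "up" else "down"
    data.frame(gene_id = d$gene_id[1], best_probe = d$probe_id[best],
               best_log2fc = d$log2fc[best], best_p = d$p_value[best],
               significant = significant, direction = direction,
               conflicted = conflicted, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$gene_id), ]
}

# Build an ef_network directly from an edge table (bypasses build_network).
make_network <- function(edges) {
  edges$synergy_group <- edges$synergy_group %||% NA_character_
  if (is.null(edges$evidence)) edges$evidence <- ""
  node_ids <- unique(c(edges$source, edges$target))
  nodes <- data.frame(id = node_ids,
                      role = ifelse(node_ids %in% edges$source, "TF", "gene"),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "ef_network")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Brute-force motif enumeration over ordered subsequences of tf_order.
brute_motifs <- function(edges, tf_order) {
  has_edge <- function(a, b, sign = NULL) {
    hit <- edges$source == a & edges$target == b
    if (!is.null(sign)) hit <- hit & edges$sign == sign
    any(hit)
  }
  auto <- edges[edges$source == edges$target & edges$source %in% tf_order, ,
                drop = FALSE]
  oi <- function(x) match(x, tf_order)
  fb <- edges[edges$source %in% tf_order & edges$target %in% tf_order &
                edges$source != edges$target &
                oi(edges$source) > oi(edges$target), , drop = FALSE]
  k <- length(tf_order)
  valid <- list()
  for (size in 2:max(2, k)) {
    if (size > k) break
    combos <- utils::combn(k, size, simplify = FALSE)
    for (cb in combos) {
      path <- tf_order[cb]
      ok <- all(vapply(seq_len(size - 1L), function(i) {
        has_edge(path[i], path[i + 1L], "+")
      }, logical(1)))
      if (ok) valid[[length(valid) + 1L]] <- path
    }
  }
  is_maximal <- function(path) {
    h <- path[1]; t <- path[length(path)]
    before <- tf_order[oi(tf_order) < oi(h)]
    after <- tf_order[oi(tf_order) > oi(t)]
    !any(vapply(before, function(u) has_edge(u, h, "+"), logical(1))) &&
      !any(vapply(after, function(w) has_edge(t, w, "+"), logical(1)))
  }
  chains <- Filter(is_maximal, valid)
  list(
    chains = sort(vapply(chains, paste, character(1), collapse = ">")),
    feedback = sort(paste(fb$source, fb$sign, fb$target)),
    auto = sort(paste(auto$source, auto$sign, auto$target))
  )
}

# Canonical form of a find_motifs() result for comparison.
motif_canonical <- function(m) {
  list(
    chains = sort(vapply(m$feedforward_chains, paste, character(1),
                         collapse = ">")),
    feedback = sort(paste(m$feedback_edges$source, m$feedback_edges$sign,
                          m$feedback_edges$target)),
    auto = sort(paste(m$autoregulation$source, m$autoregulation$sign,
                      m$autoregulation$target))
  )
}

# Random signed digraph over the given nodes (possibly with self-loops).
random_signed_digraph <- function(nodes, p_edge = 0.4) {
  rows <- list()
  for (a in nodes) for (b in nodes) {
    r <- stats::runif(1)
    if (r < p_edge) {
      rows[[length(rows) + 1L]] <- data.frame(
        source = a, target = b,
        sign = if (stats::runif(1) < 0.5) "+" else "-",
        synergy_group = NA_character_, evidence = "",
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(source = character(), target = character(),
                      sign = character(), synergy_group = character(),
                      evidence = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# Independent exact Spearman permutation p (recursive permutation builder
# distinct from the package's enumerator).
exact_perm_p <- function(x) {
  n <- length(x)
  perm_list <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perm_list(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  rho_obs <- suppressWarnings(stats::cor(rank(x), seq_len(n)))
  rhos <- vapply(perm_list(seq_len(n)), function(p) {
    suppressWarnings(stats::cor(rank(x[p]), seq_len(n)))
  }, numeric(1))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}
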