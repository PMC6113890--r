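#' Generate non-overlapping synthetic gene models
#'
#' Places `n_genes` gene loci across `n_chroms` chromosomes with lengths
#' sampled uniformly from `gene_length_range` and a guaranteed minimum
#' edge-to-edge gap between neighbouring genes on the same chromosome.
#' Coordinates are 0-based, half-open (BED convention).
#'
#' @param n_genes Number of genes (>= 1).
#' @param n_chroms Number of chromosomes; genes are distributed evenly.
#' @param min_gap_bp Minimum gap (bp) between adjacent genes on a chromosome.
#' @param chrom_length_bp Length of every chromosome.
#' @param gene_length_range Two integers, min/max gene length in bp.
#' @param seed RNG seed; identical seeds yield identical tables.
#' @return Data frame with columns `gene_id`, `symbol`, `chrom`, `start`,
#'   `end`, `strand`, sorted by chromosome then start.
#' @examples
#' gm <- generate_gene_models(10, n_chroms = 2, seed = 7)
#' head(gm)
#' @export
generate_gene_models <- function(n_genes, n_chroms = 5L, min_gap_bp = 120000L,
                                 chrom_length_bp = 4e7,
                                 gene_length_range = c(1000L, 100000L),
                                 seed = 1L) {
  if (n_genes < 1L) stop_ef("n_genes must be >= 1")
  if (min_gap_bp < 0L) stop_ef("min_gap_bp must be >= 0")
  if (n_chroms < 1L) stop_ef("n_chroms must be >= 1")
  n_genes <- as.integer(n_genes)
  n_chroms <- as.integer(n_chroms)
  # round-robin assignment of genes to chromosomes
  chrom_of <- rep(seq_len(n_chroms), length.out = n_genes)
  with_seed(sub_seed(seed, "gene_models"), {
    rows <- vector("list", n_chroms)
    gid <- 0L
    for (ch in seq_len(n_chroms)) {
      k <- sum(chrom_of == ch)
      if (k == 0L) next
      lens <- floor(runif(k, gene_length_range[1], gene_length_range[2] + 1))
      free <- chrom_length_bp - sum(lens) - (k - 1) * min_gap_bp
      if (free < 0) {
        stop_ef("cannot place ", k, " genes on a ", chrom_length_bp,
                " bp chromosome with min_gap_bp = ", min_gap_bp)
      }
      # distribute the free space as extra gaps before each gene and after
      # the last one, via a random composition
      w <- runif(k + 1)
      extra <- floor(free * w / sum(w))
      starts <- numeric(k)
      pos <- 0
      for (i in seq_len(k)) {
        pos <- pos + extra[i] + if (i > 1L) min_gap_bp else 0
        starts[i] <- pos
        pos <- pos + lens[i]
      }
      ids <- gid + seq_len(k)
      gid <- gid + k
      rows[[ch]] <- data.frame(
        gene_id = sprintf("g%04d", ids),
        symbol = sprintf("Gene%04d", ids),
        chrom = sprintf("chr%d", ch),
        start = starts,
        end = starts + lens,
        strand = sample(c("+", "-"), k, replace = TRUE),
        stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, rows)
    out <- out[order(out$chrom, out$start), , drop = FALSE]
    rownames(out) <- NULL
    validate_gene_models(out)
    out
  })
}

validate_gene_models <- function(genes) {
  req <- c("gene_id", "symbol", "chrom", "start", "end", "strand")
  missing <- setdiff(req, names(genes))
  if (length(missing)) stop_ef("gene model table lacks column(s): ",
                               paste(missing, collapse = ", "))
  if (anyDuplicated(genes$gene_id) > 0L) {
    stop_ef("duplicate gene_id: ",
            paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  }
  bad <- which(!(genes$start < genes$end))
  if (length(bad)) {
    stop_ef("gene model row ", bad[1], " (", genes$gene_id[bad[1]],
            "): start must be < end")
  }
  if (any(genes$start < 0)) stop_ef("gene model starts must be >= 0")
  if (any(!genes$strand %in% c("+", "-", "."))) {
    stop_ef("gene strand must be one of +, -, .")
  }
  invisible(genes)
}

#' Generate TF ChIP-seq peaks realising a planted binding table
#'
#' For every `(tf, gene, bound = TRUE)` entry in `truth_binding`, one peak is
#' placed either inside the gene body or with an edge-to-edge gap of at most
#' `window_bp`, so the downstream binding rule recovers the entry. Decoy
#' peaks are placed with a gap strictly greater than `window_bp` from every
#' gene, so they never produce a binding call. Placement is rejected (with an
#' error) when the genome is too dense to honour these guarantees.
#'
#' @param gene_models Gene model table (see [generate_gene_models()]).
#' @param truth_binding Data frame with columns `tf`, `gene_id`, `bound`.
#' @param decoy_per_tf Number of decoy peaks per TF.
#' @param window_bp Binding window in bp (default 50000).
#' @param peak_width_range Two integers, min/max peak width.
#' @param chrom_length_bp Chromosome length used for bounds checking.
#' @param seed RNG seed.
#' @return Data frame with columns `peak_id`, `tf`, `chrom`, `start`, `end`,
#'   `score` (0-based half-open coordinates).
#' @export
generate_peaks <- function(gene_models, truth_binding, decoy_per_tf = 30L,
                           window_bp = 50000L, peak_width_range = c(200L, 1000L),
                           chrom_length_bp = 4e7, seed = 1L) {
  if (window_bp <= 0L) stop_ef("window_bp must be > 0")
  validate_gene_models(gene_models)
  tb <- truth_binding[truth_binding$bound, , drop = FALSE]
  unknown <- setdiff(tb$gene_id, gene_models$gene_id)
  if (length(unknown)) {
    stop_ef("truth_binding references unknown gene(s): ",
            paste(unknown, collapse = ", "))
  }
  tfs <- unique(truth_binding$tf)
  if (length(tfs) == 0L && decoy_per_tf > 0L) tfs <- "TF1"
  gi <- match(tb$gene_id, gene_models$gene_id)

  # gap from a candidate peak [s, e) to every gene on the same chromosome
  min_gap_to_genes <- function(chrom, s, e, genes) {
    g <- genes[genes$chrom == chrom, , drop = FALSE]
    if (nrow(g) == 0L) return(Inf)
    min(pmax(0, pmax(g$start - e, s - g$end)))
  }
  gaps_for_tf_genes <- function(chrom, s, e, genes, idx) {
    # gap to each gene row in idx (same chrom assumed checked by caller)
    pmax(0, pmax(genes$start[idx] - e, s - genes$end[idx]))
  }

  with_seed(sub_seed(seed, "peaks"), {
    rows <- list()
    for (i in seq_len(nrow(tb))) {
      g <- gene_models[gi[i], ]
      tf <- tb$tf[i]
      # genes of this TF that are allowed to be within the window
      allowed <- gene_models$gene_id %in% tb$gene_id[tb$tf == tf]
      placed <- FALSE
      for (try in seq_len(200L)) {
        w <- floor(runif(1, peak_width_range[1], peak_width_range[2] + 1))
        mode <- sample(c("body", "flank"), 1L)
        if (mode == "body" && (g$end - g$start) > w) {
          s <- floor(runif(1, g$start, g$end - w))
        } else {
          off <- floor(runif(1, 0, window_bp + 1 - w))
          s <- if (runif(1) < 0.5) g$start - off - w else g$end + off
        }
        e <- s + w
        if (s < 0 || e > chrom_length_bp) next
        # the peak must not create binding for any other, non-bound gene
        same <- which(gene_models$chrom == g$chrom)
        gp <- gaps_for_tf_genes(g$chrom, s, e, gene_models, same)
        ok_target <- gp[same == gi[i]] <= window_bp
        viol <- same[gp <= window_bp & !allowed[same]]
        if (isTRUE(ok_target) && length(viol) == 0L) {
          rows[[length(rows) + 1L]] <- data.frame(
            peak_id = sprintf("%s_pk%04d", tf, length(rows) + 1L),
            tf = tf, chrom = g$chrom, start = s, end = e, score = round(runif(1, 10, 100), 2),
            stringsAsFactors = FALSE
          )
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop_ef("could not place a planted peak for ", tf, " at ", g$gene_id,
                " without creating unplanted binding; genome too dense")
      }
    }
    chroms <- unique(gene_models$chrom)
    for (tf in tfs) {
      k <- 0L
      tries <- 0L
      while (k < decoy_per_tf) {
        tries <- tries + 1L
        if (tries > 500L * max(1L, decoy_per_tf)) {
          stop_ef("could not place decoy peaks > ", window_bp,
                  " bp from all genes; genome too dense")
        }
        w <- floor(runif(1, peak_width_range[1], peak_width_range[2] + 1))
        chrom <- sample(chroms, 1L)
        s <- floor(runif(1, 0, chrom_length_bp - w))
        e <- s + w
        if (min_gap_to_genes(chrom, s, e, gene_models) <= window_bp) next
        k <- k + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          peak_id = sprintf("%s_decoy%04d", tf, k),
          tf = tf, chrom = chrom, start = s, end = e, score = round(runif(1, 10, 100), 2),
          stringsAsFactors = FALSE
        )
      }
    }
    out <- do.call(rbind, rows)
    if (is.null(out)) {
      out <- data.frame(peak_id = character(), tf = character(), chrom = character(),
                        start = numeric(), end = numeric(), score = numeric(),
                        stringsAsFactors = FALSE)
    }
    out <- out[order(out$tf, out$chrom, out$start), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}
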