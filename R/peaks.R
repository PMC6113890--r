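#' Edge-to-edge gap between a peak and a gene body
#'
#' Distance rule used throughout the package: intervals are 0-based
#' half-open; intersecting intervals have gap 0, otherwise the gap is the
#' number of bases strictly between them. Strand is ignored (the binding
#' window is symmetric upstream and downstream of the gene body).
#'
#' @param peak_start,peak_end Peak interval (vectorised).
#' @param gene_start,gene_end Gene interval (vectorised).
#' @return Non-negative integer gap(s) in bp.
#' @examples
#' peak_gene_gap(150, 250, 200, 500)  # overlap -> 0
#' peak_gene_gap(0, 100, 150, 300)    # -> 50
#' @export
peak_gene_gap <- function(peak_start, peak_end, gene_start, gene_end) {
  if (any(peak_start >= peak_end) || any(gene_start >= gene_end)) {
    stop_ef("intervals must satisfy start < end")
  }
  pmax(0, pmax(gene_start - peak_end, peak_start - gene_end))
}

validate_peaks <- function(peaks) {
  req <- c("peak_id", "tf", "chrom", "start", "end")
  missing <- setdiff(req, names(peaks))
  if (length(missing)) stop_ef("peak table lacks column(s): ",
                               paste(missing, collapse = ", "))
  if (any(!nzchar(peaks$tf))) stop_ef("peak tf labels must be non-empty")
  bad <- which(!(peaks$start < peaks$end))
  if (length(bad)) stop_ef("peak row ", bad[1], ": start must be < end")
  invisible(peaks)
}

# GRanges from a 0-based half-open table (1-based closed internally).
as_granges0 <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# Drop peaks on chromosomes absent from the gene set, with a warning.
drop_foreign_peaks <- function(peaks, genes, verbose = TRUE) {
  foreign <- !(peaks$chrom %in% unique(genes$chrom))
  if (any(foreign)) {
    warning(sum(foreign), " peak(s) on chromosome(s) absent from the gene set",
            " were ignored: ",
            paste(unique(peaks$chrom[foreign]), collapse = ", "),
            call. = FALSE)
    peaks <- peaks[!foreign, , drop = FALSE]
  }
  peaks
}

#' Annotate each peak to its closest gene within a window
#'
#' Assigns every peak the gene minimising the edge-to-edge gap, provided the
#' gap does not exceed `window_bp` (inclusive); otherwise the peak is left
#' unassigned. Ties are broken by smaller gap, then smaller gene start, then
#' lexicographic gene id. Interval matching uses an indexed overlap query
#' (GenomicRanges) over the window-extended gene bodies.
#'
#' @param peaks Peak table (`peak_id`, `tf`, `chrom`, `start`, `end`).
#' @param genes Gene model table.
#' @param window_bp Maximum gap in bp (default 50000, inclusive).
#' @return The peak table with added columns `gene_id` (NA when unassigned)
#'   and `gap_bp` (NA when unassigned).
#' @export
annotate_peak <- function(peaks, genes, window_bp = 50000L) {
  validate_peaks(peaks)
  validate_gene_models(genes)
  peaks$gene_id <- NA_character_
  peaks$gap_bp <- NA_real_
  if (nrow(peaks) == 0L || nrow(genes) == 0L) return(peaks)
  keep <- peaks$chrom %in% unique(genes$chrom)
  if (any(keep)) {
    pg <- as_granges0(peaks[keep, , drop = FALSE])
    gg <- as_granges0(genes)
    hits <- GenomicRanges::findOverlaps(pg, gg, maxgap = window_bp)
    if (length(hits)) {
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      gap <- GenomicRanges::distance(pg[qh], gg[sh])
      ord <- order(qh, gap, genes$start[sh], genes$gene_id[sh])
      first <- ord[!duplicated(qh[ord])]
      keep_idx <- which(keep)
      peaks$gene_id[keep_idx[qh[first]]] <- genes$gene_id[sh[first]]
      peaks$gap_bp[keep_idx[qh[first]]] <- gap[first]
    }
  }
  peaks
}

# Minimum edge-to-edge gap from each gene to any peak, by sorted sweep
# over peak starts per chromosome (NA when the chromosome has no peak).
# For the left side the closest peak is the one with the largest end among
# those starting before the gene end (cumulative max over the start-sorted
# peaks); for the right side it is the first peak starting at or after the
# gene end.
min_gap_sweep <- function(genes, peaks) {
  out <- rep(NA_real_, nrow(genes))
  for (ch in unique(genes$chrom)) {
    pi <- which(peaks$chrom == ch)
    if (!length(pi)) next
    gi <- which(genes$chrom == ch)
    ps <- peaks$start[pi]
    pe <- peaks$end[pi]
    ord <- order(ps)
    ps <- ps[ord]
    pe_cummax <- cummax(pe[ord])
    g_start <- genes$start[gi]
    g_end <- genes$end[gi]
    j <- findInterval(g_end - 0.5, ps)  # peaks starting before the gene end
    gap_left <- ifelse(j > 0, pmax(0, g_start - pe_cummax[pmax(j, 1L)]), Inf)
    nxt <- j + 1L
    gap_right <- ifelse(nxt <= length(ps), ps[pmin(nxt, length(ps))] - g_end, Inf)
    out[gi] <- pmin(gap_left, gap_right)
  }
  out
}

#' Call gene-level TF binding with the 50 kb rule
#'
#' A gene is called bound by a TF when any peak of that TF overlaps the gene
#' body or lies within `window_bp` of it (gap of exactly `window_bp` counts
#' as bound). One call is emitted for every (gene, TF) pair over the TFs
#' present in the peak input. Peaks on chromosomes absent from the gene set
#' are ignored with a warning.
#'
#' @param peaks Peak table.
#' @param genes Gene model table.
#' @param window_bp Binding window in bp (>= 0; default 50000).
#' @return Data frame with columns `gene_id`, `tf`, `bound`, `min_gap_bp`
#'   (NA when the TF has no same-chromosome peak), and `supporting_peak_ids`
#'   (comma-separated; empty unless bound).
#' @export
call_binding <- function(peaks, genes, window_bp = 50000L) {
  validate_peaks(peaks)
  validate_gene_models(genes)
  if (window_bp < 0L) stop_ef("window_bp must be >= 0")
  peaks <- drop_foreign_peaks(peaks, genes)
  tfs <- sort(unique(peaks$tf))
  gg <- as_granges0(genes)
  pg_all <- as_granges0(peaks)
  out <- list()
  for (tf in tfs) {
    sel <- which(peaks$tf == tf)
    pk <- peaks[sel, , drop = FALSE]
    res <- data.frame(
      gene_id = genes$gene_id, tf = tf, bound = FALSE,
      min_gap_bp = NA_real_, supporting_peak_ids = "",
      stringsAsFactors = FALSE
    )
    if (nrow(pk)) {
      res$min_gap_bp <- min_gap_sweep(genes, pk)
      res$bound <- !is.na(res$min_gap_bp) & res$min_gap_bp <= window_bp
      hits <- GenomicRanges::findOverlaps(gg, pg_all[sel], maxgap = window_bp)
      if (length(hits)) {
        sup <- tapply(pk$peak_id[S4Vectors::subjectHits(hits)],
                      S4Vectors::queryHits(hits),
                      function(x) paste(sort(x), collapse = ","))
        res$supporting_peak_ids[as.integer(names(sup))] <- unname(sup)
      }
    }
    out[[tf]] <- res
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), tf = character(), bound = logical(),
                      min_gap_bp = numeric(), supporting_peak_ids = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
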