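#' Read gene models from BED6 or a headered TSV
#'
#' BED files are read through rtracklayer (0-based half-open on disk,
#' returned as such). The TSV dialect has a header with columns `gene_id`,
#' `symbol`, `chrom`, `start`, `end`, `strand` and 1-based inclusive
#' coordinates, converted to 0-based half-open at read time. Duplicate gene
#' ids and empty intervals are rejected with the offending row named.
#'
#' @param path File path (`.bed` or `.tsv`, decided by extension).
#' @return Gene model data frame (`gene_id`, `symbol`, `chrom`, `start`,
#'   `end`, `strand`), sorted by chromosome then start.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop_ef("file not found: ", path)
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED")
    w0 <- which(IRanges::width(gr) < 1L)
    if (length(w0)) {
      stop_ef("gene model line ", w0[1], ": start must be < end")
    }
    nm <- S4Vectors::mcols(gr)$name
    if (is.null(nm)) stop_ef("BED gene models need a name (gene_id) column")
    out <- data.frame(
      gene_id = nm,
      symbol = nm,
      chrom = as.character(GenomeInfoDb::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE
    )
    out$strand[out$strand == "*"] <- "."
  } else {
    d <- read.delim(path, stringsAsFactors = FALSE)
    req <- c("gene_id", "chrom", "start", "end", "strand")
    missing <- setdiff(req, names(d))
    if (length(missing)) stop_ef(path, ": missing column(s): ",
                                 paste(missing, collapse = ", "))
    bad <- which(!(d$start <= d$end))
    if (length(bad)) stop_ef("gene model line ", bad[1] + 1L,
                             ": start must be <= end (1-based inclusive)")
    out <- data.frame(
      gene_id = d$gene_id,
      symbol = if ("symbol" %in% names(d)) d$symbol else d$gene_id,
      chrom = d$chrom,
      start = d$start - 1L,
      end = d$end,
      strand = d$strand,
      stringsAsFactors = FALSE
    )
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  validate_gene_models(out)
}

#' Write gene models as 6-column BED
#'
#' @param genes Gene model table (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_bed <- function(genes, path) {
  validate_gene_models(genes)
  bed <- data.frame(genes$chrom, genes$start, genes$end, genes$gene_id, 0L,
                    genes$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TF peak set from BED
#'
#' @param path BED file path.
#' @param tf TF label to attach to every peak.
#' @return Peak data frame (`peak_id`, `tf`, `chrom`, `start`, `end`,
#'   `score`), 0-based half-open.
#' @export
read_peaks <- function(path, tf) {
  if (!file.exists(path)) stop_ef("file not found: ", path)
  if (!nzchar(tf)) stop_ef("tf label must be non-empty")
  gr <- rtracklayer::import(path, format = "BED")
  w0 <- which(IRanges::width(gr) < 1L)
  if (length(w0)) stop_ef("peak line ", w0[1], ": start must be < end")
  nm <- S4Vectors::mcols(gr)$name
  sc <- S4Vectors::mcols(gr)$score
  out <- data.frame(
    peak_id = if (!is.null(nm)) nm else sprintf("%s_pk%04d", tf, seq_along(gr)),
    tf = tf,
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    score = if (!is.null(sc)) as.numeric(sc) else NA_real_,
    stringsAsFactors = FALSE
  )
  validate_peaks(out)
  out
}

#' Write peaks as BED
#' @param peaks Peak table for a single TF.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  validate_peaks(peaks)
  bed <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$peak_id,
                    ifelse(is.na(peaks$score), 0, peaks$score), ".")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop_ef("file not found: ", path)
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read an expression matrix TSV (probes x samples)
#' @param path TSV with first column `probe_id`.
#' @return Numeric matrix with probe ids as rownames.
#' @export
read_expression_matrix <- function(path) {
  d <- read_tsv(path)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write an expression matrix TSV
#' @param mat Probe x sample matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path) {
  d <- data.frame(probe_id = rownames(mat), mat, check.names = FALSE,
                  stringsAsFactors = FALSE)
  write_tsv(d, path)
}
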