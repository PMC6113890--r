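test_that("peak-gene gap arithmetic matches examples and a per-base scan", {
  expect_equal(peak_gene_gap(150, 250, 200, 500), 0)
  expect_equal(peak_gene_gap(0, 100, 150, 300), 50)
  expect_error(peak_gene_gap(10, 10, 0, 5), "start < end")

  set.seed(42)
  for (i in 1:500) {
    s1 <- sample(0:300, 1); e1 <- s1 + sample(1:40, 1)
    s2 <- sample(0:300, 1); e2 <- s2 + sample(1:40, 1)
    expect_equal(peak_gene_gap(s1, e1, s2, e2), scan_gap(s1, e1, s2, e2))
  }
})

test_that("gap is symmetric in its two intervals", {
  set.seed(7)
  for (i in 1:200) {
    s1 <- sample(0:500, 1); e1 <- s1 + sample(1:50, 1)
    s2 <- sample(0:500, 1); e2 <- s2 + sample(1:50, 1)
    expect_identical(peak_gene_gap(s1, e1, s2, e2),
                     peak_gene_gap(s2, e2, s1, e1))
  }
})

test_that("annotate_peak picks the closest gene with deterministic tie-breaks", {
  genes <- data.frame(
    gene_id = c("gA", "gB"), symbol = c("gA", "gB"), chrom = "chr1",
    start = c(20000, 60000), end = c(21000, 61000), strand = "+",
    stringsAsFactors = FALSE
  )
  pk <- data.frame(peak_id = "p1", tf = "T", chrom = "chr1",
                   start = 10000, end = 10100, score = 1,
                   stringsAsFactors = FALSE)
  ann <- annotate_peak(pk, genes)
  expect_identical(ann$gene_id, "gA")
  expect_equal(ann$gap_bp, 9900)

  # beyond the window: unassigned
  pk2 <- transform(pk, start = genes$end[2] + 50001, end = genes$end[2] + 50101)
  expect_true(is.na(annotate_peak(pk2, genes)$gene_id))
  # at exactly the window: assigned
  pk3 <- transform(pk, start = genes$end[2] + 50000, end = genes$end[2] + 50100)
  expect_identical(annotate_peak(pk3, genes)$gene_id, "gB")

  # equidistant genes: smaller start, then lexicographic id
  genes2 <- data.frame(
    gene_id = c("gC", "gB2"), symbol = c("gC", "gB2"), chrom = "chr1",
    start = c(1000, 3000), end = c(1500, 3500), strand = "+",
    stringsAsFactors = FALSE
  )
  mid <- data.frame(peak_id = "p1", tf = "T", chrom = "chr1",
                    start = 2000, end = 2500, score = 1,
                    stringsAsFactors = FALSE)
  expect_identical(annotate_peak(mid, genes2)$gene_id, "gC")
})

test_that("binding boundary at 50 kb is inclusive and monotone in window", {
  genes <- data.frame(gene_id = "g1", symbol = "g1", chrom = "chr1",
                      start = 100000, end = 101000, strand = "+",
                      stringsAsFactors = FALSE)
  at <- function(gap) data.frame(peak_id = "p", tf = "T", chrom = "chr1",
                                 start = 101000 + gap, end = 101100 + gap,
                                 score = 1, stringsAsFactors = FALSE)
  expect_true(call_binding(at(50000), genes)$bound)
  expect_false(call_binding(at(50001), genes)$bound)
  # enlarging the window never unbinds
  for (gap in c(0, 1, 49999, 50000, 50001, 80000)) {
    b_small <- call_binding(at(gap), genes, window_bp = 50000)$bound
    b_large <- call_binding(at(gap), genes, window_bp = 80000)$bound
    expect_true(!b_small || b_large)
  }
})

test_that("indexed binding calls equal the brute-force pair scan on random genomes", {
  set.seed(11)
  for (i in 1:60) {
    inst <- random_genome(n_genes = sample(2:12, 1), n_peaks = sample(2:20, 1),
                          span = 3000, max_len = 80)
    window <- sample(c(0, 10, 100, 500), 1)
    got <- suppressWarnings(call_binding(inst$peaks, inst$genes, window_bp = window))
    want <- brute_binding(inst$peaks, inst$genes, window)
    got <- got[order(got$tf, got$gene_id), ]
    want <- want[order(want$tf, want$gene_id), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got$bound, want$bound)
    expect_equal(got$min_gap_bp, want$min_gap_bp)
    expect_equal(got$supporting_peak_ids, want$supporting_peak_ids)
    ann <- annotate_peak(inst$peaks, inst$genes, window_bp = window)
    brute <- brute_annotate(inst$peaks, inst$genes, window)
    expect_equal(ann$gene_id, brute$gene_id)
    expect_equal(ann$gap_bp, brute$gap_bp)
  }
})

test_that("peaks on chromosomes absent from the gene set are dropped with a warning", {
  genes <- data.frame(gene_id = "g1", symbol = "g1", chrom = "chr1",
                      start = 0, end = 1000, strand = "+",
                      stringsAsFactors = FALSE)
  pk <- data.frame(peak_id = c("p1", "p2"), tf = "T",
                   chrom = c("chr1", "chrX"), start = c(100, 100),
                   end = c(200, 200), score = 1, stringsAsFactors = FALSE)
  expect_warning(res <- call_binding(pk, genes), "absent")
  expect_identical(res$supporting_peak_ids[res$bound], "p1")
})

test_that("gene model reader validates and round-trips BED", {
  dir <- withr::local_tempdir()
  gm <- generate_gene_models(15, n_chroms = 2, min_gap_bp = 1000,
                             chrom_length_bp = 2e6, seed = 2)
  path <- file.path(dir, "genes.bed")
  write_gene_models_bed(gm, path)
  back <- read_gene_models(path)
  expect_equal(back[, c("gene_id", "chrom", "start", "end", "strand")],
               gm[, c("gene_id", "chrom", "start", "end", "strand")])

  bad <- file.path(dir, "bad.bed")
  writeLines(c("chr1\t10\t20\tgA\t0\t+", "chr1\t30\t30\tgB\t0\t+"), bad)
  expect_error(read_gene_models(bad), "start must be < end")

  dup <- file.path(dir, "dup.bed")
  writeLines(c("chr1\t10\t20\tgA\t0\t+", "chr1\t100\t200\tgA\t0\t+"), dup)
  expect_error(read_gene_models(dup), "duplicate")

  # 1-based TSV dialect converts to half-open
  tsv <- file.path(dir, "genes.tsv")
  writeLines(c("gene_id\tsymbol\tchrom\tstart\tend\tstrand",
               "gA\tA\tchr1\t1\t100\t+"), tsv)
  g <- read_gene_models(tsv)
  expect_equal(g$start, 0)
  expect_equal(g$end, 100)
})
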