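test_that("gene model generation honours placement contracts and determinism", {
  gm1 <- generate_gene_models(1, n_chroms = 1, seed = 7)
  expect_equal(nrow(gm1), 1L)
  expect_lt(gm1$start, gm1$end)
  expect_true(gm1$strand %in% c("+", "-"))

  gm <- generate_gene_models(400, n_chroms = 5, min_gap_bp = 120000,
                             chrom_length_bp = 4e7, seed = 1)
  expect_equal(nrow(gm), 400L)
  # exhaustive pairwise same-chromosome gap check
  for (ch in unique(gm$chrom)) {
    g <- gm[gm$chrom == ch, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1L) {
      gaps <- g$start[-1] - g$end[-nrow(g)]
      expect_true(all(gaps >= 120000))
    }
  }
  expect_true(all(gm$end - gm$start >= 1000 & gm$end - gm$start <= 100000))
  gm2 <- generate_gene_models(400, n_chroms = 5, min_gap_bp = 120000,
                              chrom_length_bp = 4e7, seed = 1)
  expect_identical(gm, gm2)

  expect_error(generate_gene_models(0), "n_genes")
  expect_error(
    generate_gene_models(500, n_chroms = 1, min_gap_bp = 120000,
                         chrom_length_bp = 1e6),
    "cannot place"
  )
})

test_that("planted peaks satisfy the binding rule and decoys violate it", {
  gm <- generate_gene_models(20, n_chroms = 2, min_gap_bp = 150000,
                             chrom_length_bp = 1e7, seed = 3)
  truth <- data.frame(tf = "Tbr1", gene_id = "g0001", bound = TRUE,
                      stringsAsFactors = FALSE)
  pk <- generate_peaks(gm, truth, decoy_per_tf = 0, chrom_length_bp = 1e7,
                       seed = 5)
  expect_equal(nrow(pk), 1L)
  g <- gm[gm$gene_id == "g0001", ]
  expect_identical(pk$chrom, g$chrom)
  expect_lte(pair_gap(pk$start, pk$end, g$start, g$end), 50000)

  # decoys only: brute-force every peak x gene gap
  decoys <- generate_peaks(gm, truth[0, ], decoy_per_tf = 10,
                           window_bp = 50000, chrom_length_bp = 1e7, seed = 5)
  expect_equal(nrow(decoys), 10L)
  for (j in seq_len(nrow(decoys))) {
    gaps <- vapply(seq_len(nrow(gm)), function(i) {
      if (gm$chrom[i] != decoys$chrom[j]) return(Inf)
      pair_gap(decoys$start[j], decoys$end[j], gm$start[i], gm$end[i])
    }, numeric(1))
    expect_gt(min(gaps), 50000)
  }
})

test_that("generated peaks round-trip through binding calls to the truth", {
  cfg <- default_sim_config(n_genes = 60, seed = 17)
  truth <- make_planted_truth(cfg)
  gm <- generate_gene_models(cfg$n_genes, cfg$n_chroms, cfg$min_gap_bp,
                             cfg$chrom_length_bp, seed = cfg$seed)
  pk <- generate_peaks(gm, truth$binding, cfg$decoy_per_tf, cfg$window_bp,
                       chrom_length_bp = cfg$chrom_length_bp, seed = cfg$seed)
  calls <- call_binding(pk, gm, window_bp = cfg$window_bp)
  called <- sort(paste(calls$tf[calls$bound], calls$gene_id[calls$bound]))
  planted <- sort(paste(truth$binding$tf[truth$binding$bound],
                        truth$binding$gene_id[truth$binding$bound]))
  expect_identical(called, planted)
})

test_that("expression generator plants exact effects at zero noise", {
  design <- experiment_design()
  truth <- structure(list(
    celltype = data.frame(gene_id = c("g0001", "g0002"),
                          cell_type_label = "none", cortex_specific = FALSE,
                          gradient_label = "none", stringsAsFactors = FALSE),
    regulation = data.frame(tf = "Tbr2", gene_id = "g0001",
                            mode = "activates", effect_log2fc = 1.0,
                            stringsAsFactors = FALSE),
    binding = data.frame(tf = "Tbr2", gene_id = "g0001", bound = TRUE,
                         stringsAsFactors = FALSE)
  ), class = "ef_truth")
  expr <- generate_expression(design, truth, probes_per_gene = 2,
                              noise_sd = 0, seed = 4)
  sheet <- expr$sample_sheet
  mut <- sheet$sample_id[sheet$genotype == "tbr2_cko" & sheet$experiment == "MA1"]
  ctl <- sheet$sample_id[sheet$genotype == "control" & sheet$experiment == "MA1"]
  lfc <- rowMeans(expr$matrix[, mut, drop = FALSE]) -
    rowMeans(expr$matrix[, ctl, drop = FALSE])
  expect_equal(unname(lfc[expr$probe_map$gene_id == "g0001"]), c(-1, -1))
  expect_equal(unname(lfc[expr$probe_map$gene_id == "g0002"]), c(0, 0))
})

test_that("default design has the reference replicate counts", {
  sheet <- design_sample_sheet(experiment_design())
  ma2 <- sheet[sheet$experiment == "MA2", ]
  counts <- table(ma2$genotype)
  expect_equal(as.integer(counts[c("control", "tbr1_ko", "tbr2_cko", "tbr1_tbr2_dko")]),
               c(3L, 4L, 2L, 3L))
  expect_equal(nrow(ma2), 12L)
  expect_error(experiment_design(experiments = list(MA1 = c(control = 1L))),
               ">= 2 replicates")
})

test_that("zonal profile templates realise their labels", {
  truth <- structure(list(
    celltype = data.frame(
      gene_id = c("g0001", "g0002"),
      cell_type_label = c("RGP", "aIP+bIP"),
      cortex_specific = FALSE, gradient_label = "none",
      stringsAsFactors = FALSE),
    regulation = data.frame(tf = character(), gene_id = character(),
                            mode = character(), effect_log2fc = numeric(),
                            stringsAsFactors = FALSE),
    binding = data.frame(tf = character(), gene_id = character(),
                         bound = logical(), stringsAsFactors = FALSE)
  ), class = "ef_truth")
  z <- generate_zonal_profiles(truth, noise_sd = 0, seed = 1)
  rgp <- as.numeric(z[z$gene_id == "g0001", c("VZ", "SVZ", "IZ", "CP")])
  expect_true(rgp[1] >= 0.5 && all(rgp[-1] < 0.5))
  bil <- as.numeric(z[z$gene_id == "g0002", c("VZ", "SVZ", "IZ", "CP")])
  expect_true(all(bil[1:2] >= 0.5) && all(bil[3:4] < 0.5))
})

test_that("gradient profiles are monotone or flat at zero noise", {
  truth <- structure(list(
    celltype = data.frame(
      gene_id = c("g0001", "g0002"),
      cell_type_label = "none", cortex_specific = FALSE,
      gradient_label = c("high_caudal", "none"),
      stringsAsFactors = FALSE),
    regulation = data.frame(tf = character(), gene_id = character(),
                            mode = character(), effect_log2fc = numeric(),
                            stringsAsFactors = FALSE),
    binding = data.frame(tf = character(), gene_id = character(),
                         bound = logical(), stringsAsFactors = FALSE)
  ), class = "ef_truth")
  p <- generate_gradient_profiles(truth, n_bins = 5, slope = 1, noise_sd = 0,
                                  seed = 1)
  hc <- as.numeric(p[p$gene_id == "g0001", paste0("bin_", 1:5)])
  expect_true(all(diff(hc) > 0))
  fl <- as.numeric(p[p$gene_id == "g0002", paste0("bin_", 1:5)])
  expect_equal(diff(fl), rep(0, 4))
  expect_error(generate_gradient_profiles(truth, n_bins = 2), "n_bins")
})

test_that("planted truth is internally consistent and simulation files are deterministic", {
  cfg <- default_sim_config(n_genes = 80, seed = 5)
  truth <- make_planted_truth(cfg)
  # synergy genes are bound by both TFs; regulated genes by their TF
  syn <- truth$regulation[truth$regulation$tf == "Tbr1+Tbr2", ]
  for (g in syn$gene_id) {
    expect_true(any(truth$binding$tf == "Tbr1" & truth$binding$gene_id == g))
    expect_true(any(truth$binding$tf == "Tbr2" & truth$binding$gene_id == g))
  }
  cfg_run <- default_config(seed = 5, n_genes = 80)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_inputs(cfg_run, d1, verbose = FALSE)
  simulate_inputs(cfg_run, d2, verbose = FALSE)
  f1 <- list.files(d1)
  expect_identical(f1, list.files(d2))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})
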