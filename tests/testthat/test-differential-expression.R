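make_matrix <- function(values_by_sample) {
  m <- do.call(cbind, values_by_sample)
  rownames(m) <- sprintf("pr%02d", seq_len(nrow(m)))
  m
}

sheet_for <- function(ids, genotype, experiment = "MA1") {
  data.frame(sample_id = ids, genotype = genotype, experiment = experiment,
             lineage_fraction = "bulk", replicate = seq_along(ids),
             stringsAsFactors = FALSE)
}

test_that("probe_de matches stats::t.test on random group pairs", {
  set.seed(3)
  for (i in 1:200) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    a <- matrix(rnorm(5 * na), 5); b <- matrix(rnorm(5 * nb), 5)
    mat <- cbind(a, b)
    colnames(mat) <- sprintf("s%02d", seq_len(na + nb))
    rownames(mat) <- sprintf("pr%02d", 1:5)
    sheet <- rbind(sheet_for(colnames(mat)[1:na], "tbr1_ko"),
                   sheet_for(colnames(mat)[(na + 1):(na + nb)], "control"))
    res <- probe_de(mat, sheet, "tbr1_ko", "control", "MA1", verbose = FALSE)
    for (r in 1:5) {
      tt <- t.test(a[r, ], b[r, ])
      expect_equal(res$p_value[r], tt$p.value, tolerance = 1e-12)
      expect_equal(res$log2fc[r], unname(diff(rev(tt$estimate))),
                   tolerance = 1e-12)
    }
  }
})

test_that("small groups fall back to the pooled-variance Student test", {
  set.seed(9)
  mat <- matrix(rnorm(10 * 5), 10)
  colnames(mat) <- sprintf("s%d", 1:5)
  rownames(mat) <- sprintf("pr%02d", 1:10)
  sheet <- rbind(sheet_for(colnames(mat)[1:2], "tbr2_cko"),
                 sheet_for(colnames(mat)[3:5], "control"))
  expect_message(
    res <- probe_de(mat, sheet, "tbr2_cko", "control", "MA1"),
    "pooled"
  )
  expect_true(all(res$method == "pooled"))
  for (r in 1:10) {
    tt <- t.test(mat[r, 1:2], mat[r, 3:5], var.equal = TRUE)
    expect_equal(res$p_value[r], tt$p.value, tolerance = 1e-12)
  }
})

test_that("identical groups give zero log2FC and no significance", {
  vals <- c(1.2, 3.4, 5.6)
  mat <- matrix(c(vals, vals), nrow = 1)
  colnames(mat) <- sprintf("s%d", 1:6)
  rownames(mat) <- "pr01"
  sheet <- rbind(sheet_for(colnames(mat)[1:3], "tbr1_ko"),
                 sheet_for(colnames(mat)[4:6], "control"))
  res <- probe_de(mat, sheet, "tbr1_ko", "control", "MA1", verbose = FALSE)
  expect_equal(res$log2fc, 0)
  expect_gt(res$p_value, 0.05)
  expect_false(res$significant)
})

test_that("reversing the contrast negates log2FC and preserves p", {
  set.seed(21)
  mat <- matrix(rnorm(20 * 7), 20)
  colnames(mat) <- sprintf("s%d", 1:7)
  rownames(mat) <- sprintf("pr%02d", 1:20)
  sheet <- rbind(sheet_for(colnames(mat)[1:4], "tbr1_ko"),
                 sheet_for(colnames(mat)[5:7], "control"))
  ab <- probe_de(mat, sheet, "tbr1_ko", "control", "MA1", verbose = FALSE)
  ba <- probe_de(mat, sheet, "control", "tbr1_ko", "MA1", verbose = FALSE)
  expect_equal(ab$log2fc, -ba$log2fc)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
})

test_that("gene aggregation applies the min-p and conflicted rules", {
  probes <- data.frame(
    probe_id = c("gA_p1", "gA_p2", "gB_p1"),
    group_a = "GFP_pos", group_b = "GFP_neg", experiment = "LIN",
    n_a = 4L, n_b = 4L,
    log2fc = c(0.9, -0.7, 0.5), t = NA_real_, df = NA_real_,
    p_value = c(0.01, 0.02, 0.2), method = "welch",
    stringsAsFactors = FALSE
  )
  probes$significant <- probes$p_value < 0.05
  attr(probes, "orientation") <- "a_vs_b"
  pm <- data.frame(probe_id = probes$probe_id,
                   gene_id = sub("_p[0-9]+$", "", probes$probe_id),
                   stringsAsFactors = FALSE)
  gs <- gene_de(probes, pm)
  gA <- gs[gs$gene_id == "gA", ]
  expect_true(gA$conflicted)
  expect_identical(gA$direction, "none")
  gB <- gs[gs$gene_id == "gB", ]
  expect_false(gB$conflicted)
  expect_identical(gB$direction, "none")
  expect_false(gB$significant)
})

test_that("gene aggregation equals the brute-force rule on random tables", {
  set.seed(5)
  for (i in 1:50) {
    n_genes <- sample(3:8, 1)
    probes_per <- sample(1:4, n_genes, replace = TRUE)
    gene_ids <- sprintf("g%02d", seq_len(n_genes))
    probes <- data.frame(
      probe_id = sprintf("%s_p%d", rep(gene_ids, probes_per),
                         unlist(lapply(probes_per, seq_len))),
      group_a = "m", group_b = "c", experiment = "MA1",
      n_a = 3L, n_b = 3L,
      log2fc = round(rnorm(sum(probes_per)), 3),
      t = NA_real_, df = NA_real_,
      p_value = round(runif(sum(probes_per)), 3),
      method = "welch", stringsAsFactors = FALSE
    )
    probes$significant <- probes$p_value < 0.05
    attr(probes, "orientation") <- "a_vs_b"
    pm <- data.frame(probe_id = probes$probe_id,
                     gene_id = sub("_p[0-9]+$", "", probes$probe_id),
                     stringsAsFactors = FALSE)
    got <- gene_de(probes, pm)
    want <- brute_gene_summary(transform(probes,
                                         gene_id = pm$gene_id))
    expect_equal(got$best_probe, want$best_probe)
    expect_equal(got$best_p, want$best_p)
    expect_equal(got$direction, want$direction)
    expect_equal(got$conflicted, want$conflicted)
  }
})

test_that("lineage enrichment recovers planted signs and conflicts at zero noise", {
  design <- experiment_design()
  truth <- structure(list(
    celltype = data.frame(
      gene_id = c("g0001", "g0002", "g0003"),
      cell_type_label = c("RGP", "bIP", "conflicted"),
      cortex_specific = FALSE, gradient_label = "none",
      stringsAsFactors = FALSE),
    regulation = data.frame(tf = character(), gene_id = character(),
                            mode = character(), effect_log2fc = numeric(),
                            stringsAsFactors = FALSE),
    binding = data.frame(tf = character(), gene_id = character(),
                         bound = logical(), stringsAsFactors = FALSE)
  ), class = "ef_truth")
  expr <- generate_expression(design, truth, probes_per_gene = 2,
                              noise_sd = 0, seed = 8)
  gs <- lineage_enrichment(expr$matrix, expr$sample_sheet, expr$probe_map,
                           verbose = FALSE)
  expect_identical(gs$direction[gs$gene_id == "g0001"], "down")
  expect_identical(gs$direction[gs$gene_id == "g0002"], "up")
  expect_true(gs$conflicted[gs$gene_id == "g0003"])
})

test_that("unmapped probes are excluded with a warning", {
  probes <- data.frame(
    probe_id = c("gA_p1", "orphan"),
    group_a = "m", group_b = "c", experiment = "MA1",
    n_a = 3L, n_b = 3L, log2fc = c(1, 1), t = NA_real_, df = NA_real_,
    p_value = c(0.01, 0.01), method = "welch",
    significant = TRUE, stringsAsFactors = FALSE
  )
  attr(probes, "orientation") <- "a_vs_b"
  pm <- data.frame(probe_id = "gA_p1", gene_id = "gA", stringsAsFactors = FALSE)
  expect_warning(gs <- gene_de(probes, pm), "without gene mapping")
  expect_equal(nrow(gs), 1L)
})
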