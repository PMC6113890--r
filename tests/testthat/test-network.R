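cascade_network <- function() {
  fx <- cascade_fixture()
  reg <- call_regulation(fx$binding_calls, fx$de, fx$exclusions)
  build_network(reg)
}

test_that("network assembly produces one signed edge per qualifying call", {
  empty <- build_network(data.frame(tf = character(), gene_id = character(),
                                    mode = character(), stringsAsFactors = FALSE))
  expect_equal(nrow(empty$edges), 0L)
  expect_equal(nrow(empty$nodes), 0L)

  net <- cascade_network()
  expect_equal(nrow(net$edges), 4L)
  expect_equal(nrow(net$nodes), 3L)
  expect_setequal(
    paste(net$edges$source, net$edges$sign, net$edges$target),
    c("Pax6 + Tbr2", "Tbr2 + Tbr1", "Tbr2 - Pax6", "Pax6 - Pax6")
  )
  # every edge's evidence resolves to a regulation-call row
  fx <- cascade_fixture()
  reg <- call_regulation(fx$binding_calls, fx$de, fx$exclusions)
  for (ev in net$edges$evidence) {
    parts <- strsplit(ev, ":")[[1]]
    expect_true(any(reg$tf == parts[1] & reg$gene_id == parts[2] &
                      reg$mode == parts[3]))
  }
})

test_that("synergy calls become two co-annotated edges sharing a group id", {
  calls <- data.frame(
    tf = c("Tbr1+Tbr2", "Pax6"), gene_id = c("Chd3", "Tbr2"),
    mode = c("synergistic_activates", "activates"),
    experiment = c("MA2", "P1"), stringsAsFactors = FALSE
  )
  net <- build_network(calls)
  syn <- net$edges[!is.na(net$edges$synergy_group), ]
  expect_equal(nrow(syn), 2L)
  expect_setequal(syn$source, c("Tbr1", "Tbr2"))
  expect_equal(length(unique(syn$synergy_group)), 1L)
  expect_true(all(syn$sign == "+"))
})

test_that("conflicting duplicate edges are rejected; consistent ones dedupe", {
  calls <- data.frame(
    tf = c("Pax6", "Pax6"), gene_id = c("Tbr2", "Tbr2"),
    mode = c("activates", "represses"),
    experiment = c("P1", "P1"), stringsAsFactors = FALSE
  )
  expect_error(build_network(calls), "conflicting signs")
  calls$mode <- "activates"
  net <- build_network(calls)
  expect_equal(nrow(net$edges), 1L)
})

test_that("the cascade fixture yields one feedforward chain, one feedback, one autorepression", {
  net <- cascade_network()
  m <- find_motifs(net, c("Pax6", "Tbr2", "Tbr1"))
  expect_length(m$feedforward_chains, 1L)
  expect_identical(m$feedforward_chains[[1]], c("Pax6", "Tbr2", "Tbr1"))
  expect_equal(nrow(m$feedback_edges), 1L)
  expect_identical(m$feedback_edges$source, "Tbr2")
  expect_identical(m$feedback_edges$target, "Pax6")
  expect_identical(m$feedback_edges$sign, "-")
  expect_equal(nrow(m$autoregulation), 1L)
  expect_identical(m$autoregulation$source, "Pax6")

  # purely positive chain has no feedback
  pos <- make_network(data.frame(
    source = c("A", "B"), target = c("B", "C"), sign = "+",
    synergy_group = NA_character_, evidence = "", stringsAsFactors = FALSE
  ))
  m2 <- find_motifs(pos, c("A", "B", "C"))
  expect_equal(nrow(m2$feedback_edges), 0L)
  expect_length(m2$feedforward_chains, 1L)
})

test_that("motif detection equals brute-force enumeration on random signed digraphs", {
  set.seed(53)
  for (i in 1:150) {
    n <- sample(3:6, 1)
    nodes <- LETTERS[seq_len(n)]
    edges <- random_signed_digraph(nodes, p_edge = 0.35)
    net <- make_network(edges)
    got <- motif_canonical(suppressWarnings(find_motifs(net, nodes)))
    want <- brute_motifs(edges, nodes)
    expect_identical(got, want)
  }
})

test_that("TFs missing from the declared order are excluded with a warning", {
  edges <- data.frame(source = c("A", "Z"), target = c("B", "A"), sign = "+",
                      synergy_group = NA_character_, evidence = "",
                      stringsAsFactors = FALSE)
  net <- make_network(edges)
  expect_warning(m <- find_motifs(net, c("A", "B")), "Z")
  expect_length(m$feedforward_chains, 1L)
})

test_that("summary tallies conserve edge counts and use set-union semantics", {
  net <- cascade_network()
  s <- summarize_network(net)
  per <- s$per_tf
  for (tf in per$tf) {
    n_edges <- sum(net$edges$source == tf)
    expect_equal(per$activated[per$tf == tf] + per$repressed[per$tf == tf] +
                   per$synergistic[per$tf == tf], n_edges)
  }
  # a gene that is both graded and regulated counts once in the union
  ct <- data.frame(gene_id = c("Tbr2", "Zzz"), label = c("aIP+bIP", "none"),
                   stringsAsFactors = FALSE)
  gr <- data.frame(gene_id = c("Tbr2", "Yyy"),
                   direction = c("high_caudal", "none"),
                   stringsAsFactors = FALSE)
  s2 <- summarize_network(net, ct, gr)
  expect_equal(sum(s2$union_genes == "Tbr2"), 1L)
  expect_true("Tbr2" %in% s2$union_genes)
  expect_false("Zzz" %in% s2$union_genes)
  expect_false("Yyy" %in% s2$union_genes)
})

test_that("summary tallies on a synthetic run match the planted truth tables", {
  rec <- edge_recovery(seed = 301, noise_sd = 0, n_genes = 80)
  net <- build_network(rec$regulation)
  s <- summarize_network(net)
  tru <- rec$truth$regulation
  for (tf in c("Pax6", "Tbr1", "Tbr2")) {
    expect_equal(s$per_tf$activated[s$per_tf$tf == tf],
                 sum(tru$tf == tf & tru$mode == "activates"))
    expect_equal(s$per_tf$repressed[s$per_tf$tf == tf],
                 sum(tru$tf == tf & tru$mode == "represses"))
    expect_equal(s$per_tf$synergistic[s$per_tf$tf == tf],
                 if (tf == "Pax6") 0L else sum(tru$tf == "Tbr1+Tbr2"))
  }
})

test_that("network exports round-trip (TSV) and are well-formed (SIF, GraphML)", {
  dir <- withr::local_tempdir()
  net <- cascade_network()
  tsv <- file.path(dir, "net.tsv")
  export_network(net, tsv, "tsv")
  back <- import_network_tsv(tsv)
  expect_equal(back$edges, net$edges)
  expect_equal(back$nodes, net$nodes)

  sif <- file.path(dir, "net.sif")
  export_network(net, sif, "sif")
  lines <- readLines(sif)
  expect_length(lines, 4L)
  expect_true(all(grepl("\t(activates|represses)\t", lines)))

  gml <- file.path(dir, "net.graphml")
  export_network(net, gml, "graphml")
  doc <- xml2::read_xml(gml)  # errors if malformed
  expect_match(xml2::xml_name(doc), "graphml")
  expect_error(export_network(net, tsv, "xlsx"))
})
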