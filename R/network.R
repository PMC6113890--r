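#' Assemble the signed regulatory network from calls
#'
#' One signed edge per qualifying regulation call (modes `activates`,
#' `represses`, `synergistic_*`). A synergy call is represented as two
#' edges, one per TF of the pair, sharing a `synergy_group` id so per-TF
#' tallies stay well defined. Edge sources are tagged as TFs; target roles
#' come from `node_annotations` when given, else `"gene"`.
#'
#' @param calls Regulation call table ([call_regulation()],
#'   [combine_regulation()]).
#' @param node_annotations Optional data frame with `id`, `role` (e.g.
#'   `"EF"`).
#' @return An object of class `ef_network`: list of `nodes` (id, role) and
#'   `edges` (source, target, sign, synergy_group, evidence).
#' @examples
#' calls <- data.frame(tf = "Pax6", gene_id = "Tbr2", mode = "activates",
#'                     experiment = "P1", stringsAsFactors = FALSE)
#' net <- build_network(calls)
#' net$edges
#' @export
build_network <- function(calls, node_annotations = NULL) {
  edge_modes <- c("activates", "represses",
                  "synergistic_activates", "synergistic_represses")
  keep <- calls[calls$mode %in% edge_modes, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(keep))) {
    mode <- keep$mode[i]
    sign <- if (mode %in% c("activates", "synergistic_activates")) "+" else "-"
    synergy <- startsWith(mode, "synergistic")
    sources <- if (synergy) {
      strsplit(keep$tf[i], "+", fixed = TRUE)[[1]]
    } else {
      keep$tf[i]
    }
    group <- if (synergy) paste0("syn:", keep$tf[i], ":", keep$gene_id[i]) else NA_character_
    exp_id <- if ("experiment" %in% names(keep)) keep$experiment[i] else NA_character_
    for (src in sources) {
      rows[[length(rows) + 1L]] <- data.frame(
        source = src, target = keep$gene_id[i], sign = sign,
        synergy_group = group,
        evidence = paste(keep$tf[i], keep$gene_id[i], mode, exp_id, sep = ":"),
        stringsAsFactors = FALSE
      )
    }
  }
  edges <- do.call(rbind, rows)
  if (is.null(edges)) {
    edges <- data.frame(source = character(), target = character(),
                        sign = character(), synergy_group = character(),
                        evidence = character(), stringsAsFactors = FALSE)
  }
  key <- paste(edges$source, edges$target)
  if (anyDuplicated(key) > 0L) {
    for (k in unique(key[duplicated(key)])) {
      sub <- edges[key == k, , drop = FALSE]
      if (length(unique(sub$sign)) > 1L) {
        stop_ef("conflicting signs for edge ", sub$source[1], " -> ",
                sub$target[1], "; resolve upstream")
      }
    }
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  node_ids <- unique(c(edges$source, edges$target))
  role <- ifelse(node_ids %in% edges$source, "TF", "gene")
  if (!is.null(node_annotations)) {
    hit <- match(node_ids, node_annotations$id)
    role <- ifelse(!is.na(hit) & !(node_ids %in% edges$source),
                   node_annotations$role[hit], role)
  }
  nodes <- data.frame(id = node_ids, role = role, stringsAsFactors = FALSE)
  ord <- order(edges$source, edges$target)
  edges <- edges[ord, , drop = FALSE]
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(edges) <- rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "ef_network")
}

#' @export
print.ef_network <- function(x, ...) {
  cat("ef_network:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  if (nrow(x$edges)) {
    arrows <- ifelse(x$edges$sign == "+", "->", "-|")
    cat(paste0("  ", x$edges$source, " ", arrows, " ", x$edges$target,
               ifelse(is.na(x$edges$synergy_group), "", " [synergy]")),
        sep = "\n")
  }
  invisible(x)
}

#' Detect cascade motifs in a signed regulatory network
#'
#' Motifs are defined relative to a declared TF ordering (developmental
#' order upstream -> downstream, e.g. Pax6, Tbr2, Tbr1):
#' *feedforward chains* are maximal all-positive paths whose nodes appear
#' in increasing order; *feedback edges* run from a later TF to an earlier
#' one (any sign); *autoregulation* edges are self-loops. TFs appearing in
#' the network but missing from `tf_order` are excluded from the motif scan
#' with a warning.
#'
#' @param network An `ef_network`.
#' @param tf_order Character vector of cascade TFs, upstream first.
#' @return List with `feedforward_chains` (list of node-id vectors),
#'   `feedback_edges` (edge data frame), `autoregulation` (edge data frame).
#' @export
find_motifs <- function(network, tf_order) {
  stopifnot(inherits(network, "ef_network"))
  e <- network$edges
  missing <- setdiff(unique(e$source), tf_order)
  if (length(missing)) {
    warning("TF(s) not in tf_order excluded from motif scan: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  auto <- e[e$source == e$target & e$source %in% tf_order, , drop = FALSE]
  te <- e[e$source %in% tf_order & e$target %in% tf_order &
            e$source != e$target, , drop = FALSE]
  oi <- function(x) match(x, tf_order)
  feedback <- te[oi(te$source) > oi(te$target), , drop = FALSE]
  fwd <- te[oi(te$source) < oi(te$target) & te$sign == "+", , drop = FALSE]
  # maximal increasing all-positive paths by depth-first extension
  has_pos <- function(a, b) any(fwd$source == a & fwd$target == b)
  chains <- list()
  extend <- function(path) {
    tail_tf <- path[length(path)]
    nxt <- tf_order[oi(tf_order) > oi(tail_tf)]
    nxt <- nxt[vapply(nxt, function(w) has_pos(tail_tf, w), logical(1))]
    if (!length(nxt)) {
      if (length(path) >= 2L) chains[[length(chains) + 1L]] <<- path
      return(invisible(NULL))
    }
    for (w in nxt) extend(c(path, w))
  }
  starts <- unique(fwd$source)
  starts <- starts[vapply(starts, function(v) {
    !any(fwd$target == v)  # no positive in-edge from an earlier TF
  }, logical(1))]
  for (v in starts[order(oi(starts))]) extend(v)
  rownames(feedback) <- rownames(auto) <- NULL
  list(feedforward_chains = chains, feedback_edges = feedback,
       autoregulation = auto)
}

#' Summarise network, cell-type, and gradient calls
#'
#' Produces the headline tallies of an analysis run: per-TF counts of
#' activated, repressed, and synergistically regulated genes; gene counts
#' per cell-type label and per gradient direction; and the union count of
#' genes that are cell-type-specific, graded, or directly regulated.
#'
#' @param network An `ef_network`.
#' @param celltype_calls Optional output of [classify_cell_types()].
#' @param gradient_calls Optional output of [classify_gradients()].
#' @return List of class `ef_summary` with elements `per_tf`, `synergy_pairs`,
#'   `celltype_counts`, `gradient_counts`, `union_genes`, `n_union`.
#' @export
summarize_network <- function(network, celltype_calls = NULL,
                              gradient_calls = NULL) {
  stopifnot(inherits(network, "ef_network"))
  e <- network$edges
  tfs <- sort(unique(e$source))
  per_tf <- do.call(rbind, lapply(tfs, function(tf) {
    sub <- e[e$source == tf, , drop = FALSE]
    syn <- !is.na(sub$synergy_group)
    data.frame(
      tf = tf,
      activated = sum(sub$sign == "+" & !syn),
      repressed = sum(sub$sign == "-" & !syn),
      synergistic = sum(syn),
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(per_tf)) {
    per_tf <- data.frame(tf = character(), activated = integer(),
                         repressed = integer(), synergistic = integer(),
                         stringsAsFactors = FALSE)
  }
  syn_groups <- unique(e$synergy_group[!is.na(e$synergy_group)])
  syn_pairs <- if (length(syn_groups)) {
    pair <- vapply(strsplit(syn_groups, ":"), `[`, character(1), 2L)
    as.data.frame(table(pair), stringsAsFactors = FALSE,
                  responseName = "n_genes")
  } else {
    data.frame(pair = character(), n_genes = integer(), stringsAsFactors = FALSE)
  }
  ct_counts <- if (!is.null(celltype_calls)) {
    tab <- table(factor(celltype_calls$label, levels = CELLTYPE_LABELS))
    as.data.frame(tab, stringsAsFactors = FALSE, responseName = "n_genes")
  } else {
    NULL
  }
  if (!is.null(ct_counts)) names(ct_counts)[1] <- "label"
  gr_counts <- if (!is.null(gradient_calls)) {
    tab <- table(factor(gradient_calls$direction, levels = GRADIENT_LABELS))
    as.data.frame(tab, stringsAsFactors = FALSE, responseName = "n_genes")
  } else {
    NULL
  }
  if (!is.null(gr_counts)) names(gr_counts)[1] <- "direction"
  specific <- if (!is.null(celltype_calls)) {
    celltype_calls$gene_id[celltype_calls$label %in% CELLTYPE_SPECIFIC_LABELS]
  } else character(0)
  graded <- if (!is.null(gradient_calls)) {
    gradient_calls$gene_id[gradient_calls$direction != "none"]
  } else character(0)
  regulated <- unique(e$target)
  union_genes <- sort(unique(c(specific, graded, regulated)))
  structure(
    list(per_tf = per_tf, synergy_pairs = syn_pairs,
         celltype_counts = ct_counts, gradient_counts = gr_counts,
         union_genes = union_genes, n_union = length(union_genes)),
    class = "ef_summary"
  )
}

#' @export
print.ef_summary <- function(x, ...) {
  cat("Regulation by TF:\n")
  print(x$per_tf, row.names = FALSE)
  if (nrow(x$synergy_pairs)) {
    cat("Synergy pairs:\n")
    print(x$synergy_pairs, row.names = FALSE)
  }
  if (!is.null(x$celltype_counts)) {
    nz <- x$celltype_counts[x$celltype_counts$n_genes > 0, ]
    cat("Cell-type labels:\n")
    print(nz, row.names = FALSE)
  }
  if (!is.null(x$gradient_counts)) {
    cat("Gradients:\n")
    print(x$gradient_counts, row.names = FALSE)
  }
  cat("Union of specific, graded, or regulated genes:", x$n_union, "\n")
  invisible(x)
}

#' Export a regulatory network to TSV, SIF, or GraphML
#'
#' TSV export is lossless and round-trips through [import_network_tsv()].
#' SIF uses the interaction keywords `activates`/`represses`. GraphML (via
#' igraph) carries all edge attributes.
#'
#' @param network An `ef_network`.
#' @param path Output file path.
#' @param format One of `"tsv"`, `"sif"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("tsv", "sif", "graphml")) {
  stopifnot(inherits(network, "ef_network"))
  format <- match.arg(format)
  e <- network$edges
  if (format == "tsv") {
    roles <- setNames(network$nodes$role, network$nodes$id)
    out <- cbind(e,
                 source_role = unname(roles[e$source]),
                 target_role = unname(roles[e$target]))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "sif") {
    interaction <- ifelse(e$sign == "+", "activates", "represses")
    writeLines(paste(e$source, interaction, e$target, sep = "\t"), path)
  } else {
    g <- igraph::graph_from_data_frame(
      d = transform(e, synergy_group = ifelse(is.na(synergy_group), "",
                                              synergy_group)),
      directed = TRUE,
      vertices = network$nodes
    )
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Import a network exported as TSV
#'
#' @param path TSV written by [export_network()] with `format = "tsv"`.
#' @return An `ef_network`.
#' @export
import_network_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  req <- c("source", "target", "sign", "synergy_group", "evidence",
           "source_role", "target_role")
  missing <- setdiff(req, names(d))
  if (length(missing)) stop_ef("network TSV lacks column(s): ",
                               paste(missing, collapse = ", "))
  edges <- d[, c("source", "target", "sign", "synergy_group", "evidence")]
  for (col in names(edges)) edges[[col]] <- as.character(edges[[col]])
  node_ids <- unique(c(d$source, d$target))
  role <- c(setNames(d$source_role, d$source), setNames(d$target_role, d$target))
  nodes <- data.frame(id = node_ids, role = unname(role[node_ids]),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(edges) <- rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "ef_network")
}
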