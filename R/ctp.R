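#' Assemble the tripartite compound-target-pathway network
#'
#' Builds a typed graph with three node layers and two edge types:
#' compound-target (prediction edges restricted to the key targets) and
#' target-pathway (membership of a key target in an enriched term). Node ids
#' are layer-prefixed (`cpd:`, `tgt:`, `pwy:`) so compound names can never
#' collide with gene symbols. Compound-target edges pointing at non-key
#' targets are dropped with a warning; duplicate edges collapse.
#'
#' @param compound_target_edges data.frame `compound_id, symbol`.
#' @param target_pathway_edges data.frame `symbol, term_id`.
#' @param key_targets Character vector of key-target symbols.
#' @param roster Optional list with elements `compounds`, `targets`,
#'   `pathways`: ids that must appear as nodes even when isolated (default
#'   NULL: the node set is induced by the retained edges).
#' @details With no roster, the node set is induced by the retained edges.
#'   A roster is the way to represent screened-but-unconnected compounds, as
#'   when every screened compound is displayed regardless of degree.
#' @return A `ctp_network`: list with `nodes` (id, layer, label) and
#'   `edges` (source, target, interaction), both in stable sorted order.
#' @export
assemble_ctp <- function(compound_target_edges, target_pathway_edges,
                         key_targets, roster = NULL) {
  key <- unique(canonicalize_symbol(key_targets))
  ct <- compound_target_edges
  tp <- target_pathway_edges
  if (nrow(ct)) {
    ct$symbol <- canonicalize_symbol(ct$symbol)
    bad <- !(ct$symbol %in% key)
    if (any(bad)) {
      warning("dropping ", sum(bad), " compound-target edge(s) not incident to a key target")
      ct <- ct[!bad, , drop = FALSE]
    }
    ct <- unique(ct[, c("compound_id", "symbol")])
  }
  if (nrow(tp)) {
    tp$symbol <- canonicalize_symbol(tp$symbol)
    bad <- !(tp$symbol %in% key)
    if (any(bad)) {
      warning("dropping ", sum(bad), " target-pathway edge(s) not incident to a key target")
      tp <- tp[!bad, , drop = FALSE]
    }
    tp <- unique(tp[, c("symbol", "term_id")])
  }
  cpds <- sort(unique(c(as.character(ct$compound_id),
                        as.character(roster$compounds))))
  tgts <- sort(unique(c(ct$symbol, tp$symbol,
                        canonicalize_symbol(roster$targets))))
  pwys <- sort(unique(c(as.character(tp$term_id),
                        as.character(roster$pathways))))
  nodes <- rbind(
    if (length(cpds)) data.frame(id = paste0("cpd:", cpds), layer = "compound",
                                 label = cpds, stringsAsFactors = FALSE),
    if (length(tgts)) data.frame(id = paste0("tgt:", tgts), layer = "target",
                                 label = tgts, stringsAsFactors = FALSE),
    if (length(pwys)) data.frame(id = paste0("pwy:", pwys), layer = "pathway",
                                 label = pwys, stringsAsFactors = FALSE)
  )
  if (is.null(nodes)) {
    nodes <- data.frame(id = character(0), layer = character(0),
                        label = character(0))
  }
  edges <- rbind(
    if (nrow(ct)) data.frame(source = paste0("cpd:", ct$compound_id),
                             target = paste0("tgt:", ct$symbol),
                             interaction = "compound-target",
                             stringsAsFactors = FALSE),
    if (nrow(tp)) data.frame(source = paste0("tgt:", tp$symbol),
                             target = paste0("pwy:", tp$term_id),
                             interaction = "target-pathway",
                             stringsAsFactors = FALSE)
  )
  if (is.null(edges)) {
    edges <- data.frame(source = character(0), target = character(0),
                        interaction = character(0))
  }
  edges <- unique(edges)
  edges <- edges[order(edges$interaction, edges$source, edges$target), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "ctp_network")
}

#' Node and edge counts of a C-T-P network
#' @param net A `ctp_network`.
#' @return Named counts: per-layer nodes, total nodes, per-type and total
#'   edges.
#' @export
ctp_counts <- function(net) {
  c(
    compounds = sum(net$nodes$layer == "compound"),
    targets = sum(net$nodes$layer == "target"),
    pathways = sum(net$nodes$layer == "pathway"),
    nodes = nrow(net$nodes),
    compound_target_edges = sum(net$edges$interaction == "compound-target"),
    target_pathway_edges = sum(net$edges$interaction == "target-pathway"),
    edges = nrow(net$edges)
  )
}

#' Rank compounds by degree in the C-T-P network
#'
#' Compound degree counts distinct key targets the compound is linked to.
#' Sorted by degree descending, ties broken by compound id ascending;
#' roster compounds without edges appear with degree 0 at the bottom.
#'
#' @param net A `ctp_network`.
#' @return data.frame `compound_id, degree, correlating_targets`
#'   (semicolon-joined sorted symbols).
#' @export
rank_compounds <- function(net) {
  cpd_ids <- sub("^cpd:", "", net$nodes$id[net$nodes$layer == "compound"])
  ct <- net$edges[net$edges$interaction == "compound-target", , drop = FALSE]
  src <- sub("^cpd:", "", ct$source)
  tgt <- sub("^tgt:", "", ct$target)
  ranks <- lapply(cpd_ids, function(id) {
    targets <- sort(unique(tgt[src == id]))
    data.frame(compound_id = id, degree = length(targets),
               correlating_targets = paste(targets, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- if (length(ranks)) do.call(rbind, ranks) else {
    data.frame(compound_id = character(0), degree = integer(0),
               correlating_targets = character(0))
  }
  out <- out[order(-out$degree, out$compound_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Nominate key compounds from the degree ranking
#'
#' Either the top `top_k` compounds (deterministic under ties: degree
#' descending then id ascending) or every compound with
#' `degree >= degree_min`. Exactly one rule must be given.
#'
#' @param ranks Ranking from [rank_compounds()].
#' @param top_k Positive integer, or NULL.
#' @param degree_min Non-negative degree threshold, or NULL.
#' @return data.frame subset of `ranks`.
#' @export
select_key_compounds <- function(ranks, top_k = NULL, degree_min = NULL) {
  if (is.null(top_k) == is.null(degree_min)) {
    stop("give exactly one of top_k or degree_min")
  }
  if (!is.null(top_k)) {
    if (top_k <= 0) stop("top_k must be positive")
    return(utils::head(ranks, top_k))
  }
  out <- ranks[ranks$degree >= degree_min, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a C-T-P network as Cytoscape-compatible tables
#'
#' Writes a node table (`id, layer, label, degree`) and an edge table
#' (`source, target, interaction`) as TSV, in stable sorted order, ready for
#' import into standard network viewers.
#'
#' @param net A `ctp_network`.
#' @param node_path,edge_path Output TSV paths.
#' @return Invisibly, a list with the two tables.
#' @export
export_cytoscape <- function(net, node_path, edge_path) {
  deg <- table(c(net$edges$source, net$edges$target))
  nodes <- net$nodes
  nodes$degree <- as.integer(deg[nodes$id])
  nodes$degree[is.na(nodes$degree)] <- 0L
  nodes <- nodes[order(nodes$layer, nodes$id), , drop = FALSE]
  utils::write.table(nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(net$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(nodes = nodes, edges = net$edges))
}

#' Rebuild a C-T-P network from exported tables
#' @param node_path,edge_path Paths written by [export_cytoscape()].
#' @return A `ctp_network`.
#' @export
read_ctp_tables <- function(node_path, edge_path) {
  nodes <- utils::read.delim(node_path, stringsAsFactors = FALSE)
  edges <- utils::read.delim(edge_path, stringsAsFactors = FALSE)
  nodes <- nodes[order(match(nodes$layer, c("compound", "target", "pathway")),
                       nodes$id), c("id", "layer", "label"), drop = FALSE]
  edges <- edges[order(edges$interaction, edges$source, edges$target), ,
                 drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "ctp_network")
}
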