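#' Map differentially expressed genes to orthologous core proteins
#'
#' @param gene_ids character vector of (e.g. mouse) gene ids.
#' @param ortholog_table data.frame `gene_id`, `protein_id`.
#' @return list: `core_ids` (unique mapped protein ids) and `dropped`
#'   (gene ids without a mapping).
#' @export
map_orthologs <- function(gene_ids, ortholog_table) {
  if (!nrow(ortholog_table)) stop("empty ortholog table")
  mapped <- ortholog_table[ortholog_table$gene_id %in% gene_ids, ,
                           drop = FALSE]
  dropped <- setdiff(gene_ids, mapped$gene_id)
  list(core_ids = unique(mapped$protein_id), dropped = dropped)
}

#' Build the expression-filtered first-order interaction network
#'
#' Starting from the core proteins: (1) candidate nodes are the cores plus
#' all first-order interactors of any core; (2) non-core interactors whose
#' expression detection P exceeds `p_max` are dropped (cores are never
#' expression-filtered); (3) edges induced on the remaining nodes are
#' kept; (4) only the largest connected component is retained (ties broken
#' by edge count, then by the lexicographically smallest node set).
#' Cores outside the retained component are excluded from the network but
#' listed in the dropped report.
#'
#' @param core_ids character vector of core protein ids.
#' @param interactions canonicalized interaction table
#'   (see [read_interaction_table()]).
#' @param detection data.frame `protein_id`, `detection_p` (P-value of
#'   expression detection in the filtering cell type); proteins missing
#'   from the table are treated as not detected.
#' @param p_max detection threshold (default 0.01).
#' @return list of class `"ppi_network"`: `graph` (igraph), `nodes`
#'   (data.frame id, role, detection_p), `edges`, `kept_nodes` (the
#'   expression-filtered candidate set before the connected-component
#'   restriction; monotone in `p_max`), `dropped_cores`,
#'   `dropped_interactors`.  Note the retained component itself need not
#'   grow monotonically with `p_max`: relaxing the filter can promote a
#'   different component to largest.
#' @export
build_ppi_network <- function(core_ids, interactions, detection,
                              p_max = 0.01) {
  if (!length(core_ids)) stop("core_ids must be non-empty")
  interactions <- canonicalize_interactions(interactions)
  touch_core <- interactions$protein_a %in% core_ids |
    interactions$protein_b %in% core_ids
  first <- interactions[touch_core, , drop = FALSE]
  candidates <- union(core_ids, union(first$protein_a, first$protein_b))
  det <- detection$detection_p[match(candidates, detection$protein_id)]
  det[is.na(det)] <- 1
  is_core <- candidates %in% core_ids
  expressed <- det <= p_max
  keep_node <- is_core | expressed
  nodes <- candidates[keep_node]
  dropped_interactors <- candidates[!keep_node]
  edges <- interactions[interactions$protein_a %in% nodes &
                          interactions$protein_b %in% nodes, , drop = FALSE]
  if (!nrow(edges)) {
    warning("no edges among candidate nodes; empty network")
    g <- igraph::make_empty_graph(directed = FALSE)
    return(structure(list(graph = g,
                          nodes = data.frame(id = character(0),
                                             role = character(0),
                                             detection_p = numeric(0)),
                          edges = edges[0, ],
                          kept_nodes = nodes,
                          dropped_cores = core_ids,
                          dropped_interactors = dropped_interactors),
                     class = "ppi_network"))
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    n_edges <- vapply(best, function(ci) {
      sub <- igraph::induced_subgraph(g, which(comp$membership == ci))
      igraph::ecount(sub)
    }, numeric(1))
    best <- best[n_edges == max(n_edges)]
    if (length(best) > 1) {
      key <- vapply(best, function(ci)
        paste(sort(nodes[comp$membership == ci]), collapse = "\r"),
        character(1))
      best <- best[which.min(rank(key, ties.method = "first"))]
      best <- best[1]
    }
  }
  lcc_nodes <- igraph::V(g)$name[comp$membership == best[1]]
  lcc <- igraph::induced_subgraph(g, igraph::V(g)$name %in% lcc_nodes)
  lcc_ids <- igraph::V(lcc)$name
  node_tab <- data.frame(
    id = lcc_ids,
    role = ifelse(lcc_ids %in% core_ids, "core", "interactor"),
    detection_p = det[match(lcc_ids, candidates)],
    stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(lcc)
  edge_tab <- canonicalize_interactions(
    data.frame(protein_a = el[, 1], protein_b = el[, 2],
               stringsAsFactors = FALSE))
  structure(list(graph = lcc, nodes = node_tab, edges = edge_tab,
                 kept_nodes = nodes,
                 dropped_cores = setdiff(core_ids, lcc_ids),
                 dropped_interactors = dropped_interactors),
            class = "ppi_network")
}

#' Summarize a protein-interaction network
#'
#' @param net a `"ppi_network"` from [build_ppi_network()].
#' @return list: `n_core_retained`, `n_nodes`, `n_edges`, `mean_degree`,
#'   `max_degree`.
#' @export
network_summary <- function(net) {
  n_nodes <- nrow(net$nodes)
  n_edges <- nrow(net$edges)
  deg <- if (n_nodes) igraph::degree(net$graph) else numeric(0)
  list(n_core_retained = sum(net$nodes$role == "core"),
       n_nodes = n_nodes, n_edges = n_edges,
       mean_degree = if (n_nodes) mean(deg) else 0,
       max_degree = if (n_nodes) max(deg) else 0)
}

#' @export
print.ppi_network <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf("PPI network: %d nodes (%d core) / %d edges in largest component; %d cores dropped\n",
              s$n_nodes, s$n_core_retained, s$n_edges,
              length(x$dropped_cores)))
  invisible(x)
}
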