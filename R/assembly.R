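#' Merge protein-protein interaction edge lists
#'
#' Merges one or more edge lists (as returned by [read_edge_list()]) into a
#' single comprehensive PPI network: an undirected simple graph. `(A,B)` and
#' `(B,A)` collapse to one edge, self-loops are dropped, and a node appearing
#' only in self-loops is dropped with them. All nodes get role `target`.
#' The result is independent of the order of the input lists.
#'
#' @param edge_lists list of data.frames with columns `from`, `to`.
#' @return a `typed_network` with relation `ppi` on every edge.
#' @export
merge_ppi <- function(edge_lists) {
  if (is.data.frame(edge_lists)) edge_lists <- list(edge_lists)
  if (!length(edge_lists)) stop("need at least one edge list")
  all_edges <- do.call(rbind, lapply(edge_lists, function(e) {
    data.frame(from = as.character(e$from), to = as.character(e$to),
               stringsAsFactors = FALSE)
  }))
  all_edges <- all_edges[all_edges$from != all_edges$to, , drop = FALSE]
  if (!nrow(all_edges)) {
    return(typed_network(data.frame(id = character(), role = character())))
  }
  ids <- sort(unique(c(all_edges$from, all_edges$to)))
  all_edges$relation <- "ppi"
  typed_network(data.frame(id = ids, role = "target", stringsAsFactors = FALSE),
                all_edges)
}

#' Build the weighted disease-gene network
#'
#' Keeps disease genes whose relevance score is strictly greater than
#' `min_score` and which map onto the PPI network (exact symbol match after
#' normalization), induces the PPI subgraph on them, and removes isolated
#' nodes. Relevance scores are stored as node weights; they are attributes
#' only and never enter the importance score.
#'
#' @param ppi `typed_network` from [merge_ppi()].
#' @param genes data.frame with columns `symbol`, `relevance_score`.
#' @param min_score strict lower relevance-score cutoff (default 5).
#' @return a `typed_network` of role `disease_gene` nodes; empty (with a
#'   warning) when no gene survives.
#' @export
build_disease_network <- function(ppi, genes, min_score = 5) {
  stopifnot(is_typed_network(ppi), is.finite(min_score))
  if (any(genes$relevance_score < 0)) stop("relevance scores must be nonnegative")
  sel <- genes[genes$relevance_score > min_score, , drop = FALSE]
  sel <- sel[!duplicated(sel$symbol), , drop = FALSE]
  present <- sel$symbol %in% network_nodes(ppi)$id
  sel <- sel[present, , drop = FALSE]
  if (!nrow(sel)) {
    warning("no disease gene above min_score maps onto the PPI network")
    return(typed_network(data.frame(id = character(), role = character())))
  }
  sub <- induce_network(ppi, sel$symbol)
  sub <- drop_isolated(sub)
  nodes <- network_nodes(sub)
  if (!nrow(nodes)) {
    warning("disease network empty after isolated-node removal")
    return(typed_network(data.frame(id = character(), role = character())))
  }
  nodes$role <- "disease_gene"
  nodes$weight <- sel$relevance_score[match(nodes$id, sel$symbol)]
  typed_network(nodes, network_edges(sub))
}

#' Build the bipartite component-target network
#'
#' Duplicate associations collapse to one edge. Component ids must not
#' collide with the target gene-symbol namespace.
#'
#' @param associations data.frame with columns `component`, `target`.
#' @return a `typed_network` with `component` and `target` nodes and
#'   `component_target` edges; per-node degrees are available through
#'   [ct_degrees()].
#' @export
build_ct_network <- function(associations) {
  a <- as.data.frame(associations, stringsAsFactors = FALSE)
  if (!nrow(a)) {
    return(typed_network(data.frame(id = character(), role = character())))
  }
  stopifnot(all(c("component", "target") %in% names(a)))
  a$component <- as.character(a$component)
  a$target <- as.character(a$target)
  clash <- intersect(unique(a$component), unique(a$target))
  if (length(clash)) {
    stop("component id(s) collide with target symbol namespace: ",
         paste(clash, collapse = ", "))
  }
  a <- a[!duplicated(a[c("component", "target")]), , drop = FALSE]
  nodes <- rbind(
    data.frame(id = sort(unique(a$component)), role = "component",
               stringsAsFactors = FALSE),
    data.frame(id = sort(unique(a$target)), role = "target",
               stringsAsFactors = FALSE)
  )
  typed_network(nodes, data.frame(from = a$component, to = a$target,
                                  relation = "component_target",
                                  stringsAsFactors = FALSE))
}

#' Degrees in a component-target network
#' @param ct `typed_network` from [build_ct_network()]
#' @return list with named integer vectors `component` and `target`.
#' @export
ct_degrees <- function(ct) {
  g <- as_igraph(ct)
  deg <- igraph::degree(g)
  roles <- V(g)$role
  list(component = deg[roles == "component"], target = deg[roles != "component"])
}

#' Build the merged component-target-pathogenic (C-T-P) network
#'
#' Takes the union of the component-target network and the disease-gene
#' network, marks proteins present in both as `target_and_disease_gene`, and
#' adds PPI edges among all included protein nodes (configurable via
#' `ppi_edges`). Isolated nodes are removed.
#'
#' @param ct `typed_network` from [build_ct_network()]; must be nonempty.
#' @param disease `typed_network` from [build_disease_network()].
#' @param ppi `typed_network` from [merge_ppi()].
#' @param ppi_edges `"all"` (default) adds every PPI edge among included
#'   protein nodes; `"disease_only"` adds only edges of the disease network.
#' @return a `typed_network`.
#' @export
build_ctp_network <- function(ct, disease, ppi, ppi_edges = c("all", "disease_only")) {
  ppi_edges <- match.arg(ppi_edges)
  stopifnot(is_typed_network(ct), is_typed_network(disease), is_typed_network(ppi))
  ct_nodes <- network_nodes(ct)
  if (!nrow(ct_nodes)) stop("component-target network is empty")
  d_nodes <- network_nodes(disease)

  targets <- ct_nodes$id[ct_nodes$role != "component"]
  comps <- ct_nodes$id[ct_nodes$role == "component"]
  dgenes <- d_nodes$id
  proteins <- union(targets, dgenes)

  role <- ifelse(proteins %in% targets & proteins %in% dgenes,
                 "target_and_disease_gene",
                 ifelse(proteins %in% dgenes, "disease_gene", "target"))
  weight <- d_nodes$weight[match(proteins, d_nodes$id)]
  nodes <- rbind(
    data.frame(id = comps, role = "component", weight = NA_real_,
               stringsAsFactors = FALSE),
    data.frame(id = proteins, role = role, weight = weight, stringsAsFactors = FALSE)
  )

  ct_edges <- network_edges(ct)
  prot_edges <- if (ppi_edges == "all") {
    ppi_all <- network_edges(ppi)
    ppi_all[ppi_all$from %in% proteins & ppi_all$to %in% proteins, , drop = FALSE]
  } else {
    network_edges(disease)
  }
  d_edges <- network_edges(disease)
  prot_edges <- rbind(prot_edges, d_edges)
  prot_edges$relation <- "ppi"
  edges <- rbind(ct_edges, prot_edges)
  edges <- edges[!duplicated(data.frame(pmin(edges$from, edges$to),
                                        pmax(edges$from, edges$to))), , drop = FALSE]
  drop_isolated(typed_network(nodes, edges))
}
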