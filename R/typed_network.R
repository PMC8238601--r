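#' @importFrom igraph V E vcount ecount
NULL

NODE_ROLES <- c("component", "target", "disease_gene", "target_and_disease_gene")
EDGE_RELATIONS <- c("ppi", "component_target")

#' Construct a typed network
#'
#' A `typed_network` is an undirected simple graph whose nodes carry a role
#' (`component`, `target`, `disease_gene` or `target_and_disease_gene`) and an
#' optional numeric weight (e.g. a disease relevance score), and whose edges
#' carry a relation (`ppi` or `component_target`). It is the shared container
#' for the disease-gene network, the component-target (C-T) network and the
#' merged component-target-pathogenic (C-T-P) network.
#'
#' Validity is enforced at construction: no self-loops, no duplicate edges,
#' every edge endpoint present, and component nodes only incident to
#' `component_target` edges.
#'
#' @param nodes data.frame with columns `id`, `role` and optionally `weight`.
#' @param edges data.frame with columns `from`, `to` and optionally `relation`
#'   (default `"ppi"`). Order of endpoints is irrelevant.
#' @return An object of class `typed_network`.
#' @examples
#' net <- typed_network(
#'   nodes = data.frame(id = c("TP53", "MDM2"), role = "target"),
#'   edges = data.frame(from = "TP53", to = "MDM2")
#' )
#' network_summary(net)
#' @export
typed_network <- function(nodes, edges = NULL) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "role") %in% names(nodes)))
  nodes$id <- as.character(nodes$id)
  nodes$role <- as.character(nodes$role)
  if (is.null(nodes$weight)) nodes$weight <- rep(NA_real_, nrow(nodes))
  nodes$weight <- as.numeric(nodes$weight)
  if (anyDuplicated(nodes$id)) {
    stop("duplicate node ids: ", paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  }
  bad <- setdiff(unique(nodes$role), NODE_ROLES)
  if (length(bad)) stop("unknown node role(s): ", paste(bad, collapse = ", "))

  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        relation = character(), stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    stopifnot(all(c("from", "to") %in% names(edges)))
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    if (is.null(edges$relation)) edges$relation <- "ppi"
    edges$relation <- as.character(edges$relation)
  }
  bad <- setdiff(unique(edges$relation), EDGE_RELATIONS)
  if (length(bad)) stop("unknown edge relation(s): ", paste(bad, collapse = ", "))
  missing_ep <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(missing_ep)) {
    stop("edge endpoint(s) not in node table: ", paste(missing_ep, collapse = ", "))
  }
  if (any(edges$from == edges$to)) stop("self-loops are not allowed in a typed_network")

  # canonical endpoint order, then dedupe; nodes sorted for deterministic output
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]; edges$to[swap] <- tmp
  key <- paste(edges$from, edges$to, sep = "\r")
  if (anyDuplicated(key)) {
    if (anyDuplicated(unique(cbind(key, edges$relation))[, 1])) {
      stop("duplicate edge with conflicting relation")
    }
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL

  comp <- nodes$id[nodes$role == "component"]
  if (length(comp)) {
    touch <- edges$relation != "component_target" &
      (edges$from %in% comp | edges$to %in% comp)
    if (any(touch)) stop("component nodes may only touch component_target edges")
  }

  g <- igraph::graph_from_data_frame(edges[, c("from", "to", "relation")],
                                     directed = FALSE, vertices = nodes)
  structure(list(graph = g), class = "typed_network")
}

#' @export
is_typed_network <- function(x) inherits(x, "typed_network")

#' Coerce a typed network to an igraph object
#' @param net a `typed_network`
#' @return the underlying undirected `igraph` graph with vertex attributes
#'   `role`, `weight` and edge attribute `relation`.
#' @export
as_igraph <- function(net) {
  stopifnot(is_typed_network(net))
  net$graph
}

#' Node table of a typed network
#' @param net a `typed_network`
#' @return data.frame with columns `id`, `role`, `weight`.
#' @export
network_nodes <- function(net) {
  g <- as_igraph(net)
  data.frame(id = V(g)$name, role = V(g)$role, weight = V(g)$weight,
             stringsAsFactors = FALSE)
}

#' Edge table of a typed network
#' @param net a `typed_network`
#' @return data.frame with columns `from`, `to`, `relation`, endpoints in
#'   lexicographic order within each row.
#' @export
network_edges <- function(net) {
  g <- as_igraph(net)
  if (ecount(g) == 0L) {
    return(data.frame(from = character(), to = character(),
                      relation = character(), stringsAsFactors = FALSE))
  }
  el <- igraph::as_edgelist(g)
  swap <- el[, 1] > el[, 2]
  el[swap, ] <- el[swap, c(2, 1)]
  out <- data.frame(from = el[, 1], to = el[, 2], relation = E(g)$relation,
                    stringsAsFactors = FALSE)
  out <- out[order(out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize a typed network
#'
#' @param net a `typed_network`
#' @return list with node/edge counts, counts by role and by relation,
#'   suitable for JSON export.
#' @export
network_summary <- function(net) {
  nodes <- network_nodes(net)
  edges <- network_edges(net)
  list(
    n_nodes = nrow(nodes),
    n_edges = nrow(edges),
    nodes_by_role = as.list(table(factor(nodes$role, levels = NODE_ROLES))),
    edges_by_relation = as.list(table(factor(edges$relation, levels = EDGE_RELATIONS)))
  )
}

#' @export
print.typed_network <- function(x, ...) {
  s <- network_summary(x)
  cat("typed_network:", s$n_nodes, "nodes,", s$n_edges, "edges\n")
  roles <- unlist(s$nodes_by_role)
  roles <- roles[roles > 0]
  if (length(roles)) {
    cat("  roles:", paste(sprintf("%s=%d", names(roles), roles), collapse = ", "), "\n")
  }
  invisible(x)
}

# induced subgraph on ids, preserving roles/weights/relations
induce_network <- function(net, ids) {
  g <- as_igraph(net)
  sub <- igraph::induced_subgraph(g, which(V(g)$name %in% ids))
  nodes <- data.frame(id = V(sub)$name, role = V(sub)$role,
                      weight = V(sub)$weight, stringsAsFactors = FALSE)
  edges <- if (ecount(sub)) {
    el <- igraph::as_edgelist(sub)
    data.frame(from = el[, 1], to = el[, 2], relation = E(sub)$relation,
               stringsAsFactors = FALSE)
  } else NULL
  typed_network(nodes, edges)
}

# drop nodes of degree zero
drop_isolated <- function(net) {
  g <- as_igraph(net)
  keep <- V(g)$name[igraph::degree(g) > 0]
  induce_network(net, keep)
}

#' Test two typed networks for graph equality
#'
#' Equality of node ids, roles, weights, edge sets and edge relations
#' (labelled equality, not isomorphism).
#' @param a,b `typed_network` objects
#' @return logical
#' @export
network_equal <- function(a, b) {
  isTRUE(all.equal(network_nodes(a), network_nodes(b))) &&
    isTRUE(all.equal(network_edges(a), network_edges(b)))
}
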