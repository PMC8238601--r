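#' Composite node-importance scores
#'
#' Scores every node `i` of an undirected, unweighted simple graph with the
#' composite measure
#' \deqn{W_i = \frac{n-1}{\sum_k d(i,k)} \times
#'       \frac{\sum_{j<k,\; j\neq i\neq k} t_{jk}(i)/t_{jk}}{n(n-1)/2},}
#' the product of a closeness factor (how short the node's distances to the
#' rest of the network are) and a bridging factor (the fraction of node pairs
#' whose shortest paths pass through the node, normalized by the total number
#' of unordered pairs). `t_jk` is the number of shortest paths between `j`
#' and `k` and `t_jk(i)` the number of those passing through `i`. Node
#' weights and edge relations are ignored; the graph is treated as undirected
#' and unweighted.
#'
#' By default the graph must be connected (after upstream isolated-node
#' removal) and have at least 3 nodes. With `componentwise = TRUE` a
#' disconnected graph is scored per connected component: distances to
#' unreachable nodes are excluded from the closeness denominator (the
#' numerator becomes the component size minus one), unreachable pairs
#' contribute 0 to bridging, and the bridging denominator stays the global
#' `n(n-1)/2`.
#'
#' @param net a `typed_network` or an `igraph` graph.
#' @param componentwise score disconnected graphs per component instead of
#'   erroring.
#' @return object of class `importance_scores`: list with `scores` (data.frame
#'   `id`, `role`, `closeness_factor`, `bridging_factor`, `wi`, `above_mean`),
#'   `w_avg`, and `n`.
#' @examples
#' p3 <- typed_network(data.frame(id = c("a", "b", "c"), role = "target"),
#'                     data.frame(from = c("a", "b"), to = c("b", "c")))
#' importance_scores(p3)  # center scores 1/3, leaves 0
#' @export
importance_scores <- function(net, componentwise = FALSE) {
  g <- if (is_typed_network(net)) as_igraph(net) else net
  stopifnot(igraph::is_igraph(g))
  n <- vcount(g)
  if (n < 3L) stop("importance scores need at least 3 nodes")
  comp <- igraph::components(g)
  if (comp$no > 1L && !componentwise) {
    stop("graph is disconnected (", comp$no,
         " components); use componentwise = TRUE or remove stray components")
  }

  d <- igraph::distances(g)
  reach <- is.finite(d)
  sum_d <- rowSums(ifelse(reach, d, 0))
  n_reach <- rowSums(reach) - 1L  # exclude self
  closeness_factor <- ifelse(n_reach > 0, n_reach / sum_d, 0)

  # interior pair-dependency: unordered pairs, endpoints excluded;
  # unreachable pairs contribute nothing
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  bridging_factor <- btw / (n * (n - 1) / 2)

  wi <- closeness_factor * bridging_factor
  w_avg <- mean(wi)
  role <- if (!is.null(V(g)$role)) V(g)$role else rep("target", n)
  scores <- data.frame(
    id = V(g)$name, role = role,
    closeness_factor = as.numeric(closeness_factor),
    bridging_factor = as.numeric(bridging_factor),
    wi = as.numeric(wi),
    above_mean = wi > w_avg,
    stringsAsFactors = FALSE
  )
  rownames(scores) <- NULL
  structure(list(scores = scores, w_avg = w_avg, n = n),
            class = "importance_scores")
}

#' @export
print.importance_scores <- function(x, ...) {
  cat("importance_scores over", x$n, "nodes; W_avg =", format(x$w_avg), "\n")
  cat(" ", sum(x$scores$above_mean), "node(s) strictly above the mean\n")
  invisible(x)
}

#' @export
summary.importance_scores <- function(object, ...) {
  s <- object$scores[order(-object$scores$wi), ]
  rownames(s) <- NULL
  structure(list(top = utils::head(s, 10L), w_avg = object$w_avg,
                 n = object$n, n_above = sum(s$above_mean)),
            class = "summary.importance_scores")
}

#' @export
print.summary.importance_scores <- function(x, ...) {
  cat("importance_scores:", x$n, "nodes, W_avg =", format(x$w_avg), ";",
      x$n_above, "above mean\nTop nodes:\n")
  print(x$top)
  invisible(x)
}

#' @export
plot.importance_scores <- function(x, ...) {
  s <- x$scores
  graphics::plot(s$closeness_factor, s$bridging_factor,
                 col = ifelse(s$above_mean, "firebrick", "grey40"),
                 pch = 19, xlab = "closeness factor", ylab = "bridging factor",
                 main = "Composite node importance", ...)
  invisible(x)
}

#' Extract the critical response network (CRN)
#'
#' Keeps exactly the nodes whose importance is strictly above the network
#' mean (`Wi > W_avg`), takes the induced subgraph on them, and reports the
#' non-component nodes among them as effective proteins. An empty CRN (e.g.
#' when all scores are equal) is a legal result.
#'
#' @param net the `typed_network` the scores were computed on.
#' @param scores an `importance_scores` object from [importance_scores()].
#' @return object of class `crn_result`: list with `kept_nodes`, `network`
#'   (induced `typed_network`), and `effective_proteins`.
#' @export
extract_crn <- function(net, scores) {
  stopifnot(is_typed_network(net), inherits(scores, "importance_scores"))
  ids <- network_nodes(net)$id
  if (!setequal(ids, scores$scores$id)) {
    stop("scores were not computed on this network")
  }
  kept <- scores$scores$id[scores$scores$above_mean]
  sub <- induce_network(net, kept)
  roles <- scores$scores$role[match(kept, scores$scores$id)]
  structure(list(
    kept_nodes = kept,
    network = sub,
    effective_proteins = kept[roles != "component"]
  ), class = "crn_result")
}

#' @export
print.crn_result <- function(x, ...) {
  s <- network_summary(x$network)
  cat("crn_result:", length(x$kept_nodes), "nodes kept,", s$n_edges,
      "edges retained,", length(x$effective_proteins), "effective proteins\n")
  invisible(x)
}

#' Baseline centrality scores
#'
#' Standard single-number centralities used as comparison models for the
#' composite importance score: degree (edge count), betweenness (unnormalized
#' interior pair-dependency, unordered pairs) and the local clustering
#' coefficient (0 for nodes of degree < 2). The same strict above-mean rule
#' applies downstream via [effective_proteins_by()].
#'
#' @param net a `typed_network` or igraph graph.
#' @param method one of `"degree"`, `"betweenness"`, `"clustering"`.
#' @return named numeric vector of node scores.
#' @export
baseline_scores <- function(net, method = c("degree", "betweenness", "clustering")) {
  method <- match.arg(method)
  g <- if (is_typed_network(net)) as_igraph(net) else net
  v <- switch(method,
    degree = igraph::degree(g),
    betweenness = igraph::betweenness(g, directed = FALSE, normalized = FALSE),
    clustering = {
      cc <- igraph::transitivity(g, type = "local", isolates = "zero")
      names(cc) <- V(g)$name
      cc[is.na(cc)] <- 0
      cc
    })
  stats::setNames(as.numeric(v), V(g)$name)
}

#' Effective proteins under a scoring method
#'
#' Applies a scoring method (`"composite"` for the composite importance score or a
#' baseline centrality) and the strict above-mean rule, returning the
#' non-component nodes retained.
#'
#' @param net a `typed_network`.
#' @param method `"composite"`, `"degree"`, `"betweenness"` or `"clustering"`.
#' @param componentwise passed to [importance_scores()] for `"composite"`.
#' @return character vector of effective protein ids (possibly empty).
#' @export
effective_proteins_by <- function(net, method = "composite", componentwise = FALSE) {
  nodes <- network_nodes(net)
  if (method == "composite") {
    sc <- importance_scores(net, componentwise = componentwise)
    return(extract_crn(net, sc)$effective_proteins)
  }
  v <- baseline_scores(net, method)
  kept <- names(v)[v > mean(v)]
  kept[nodes$role[match(kept, nodes$id)] != "component"]
}

#' Categorize protein targets of the C-T-P network
#'
#' Splits proteins into three pairwise disjoint categories: essential common
#' targets (component targets that are also pathogenic genes),
#' component-specific targets, and disease-specific genes.
#'
#' @param ct_targets character vector of component target symbols.
#' @param disease_genes character vector of pathogenic gene symbols.
#' @param all_proteins character vector; both inputs must be subsets of it.
#' @return list with `essential_common`, `component_specific`,
#'   `disease_specific` (sorted character vectors).
#' @export
categorize_targets <- function(ct_targets, disease_genes, all_proteins) {
  ct_targets <- unique(ct_targets); disease_genes <- unique(disease_genes)
  if (!all(ct_targets %in% all_proteins) || !all(disease_genes %in% all_proteins)) {
    stop("target and disease-gene sets must be subsets of all_proteins")
  }
  list(
    essential_common = sort(intersect(ct_targets, disease_genes)),
    component_specific = sort(setdiff(ct_targets, disease_genes)),
    disease_specific = sort(setdiff(disease_genes, ct_targets))
  )
}
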