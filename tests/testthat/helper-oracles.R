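# Independent oracles for the production algorithms. The importance oracle
# counts shortest paths by walk counting (powers of the adjacency matrix):
# the number of walks of length d(j,k) between j and k equals the number of
# shortest paths, and paths through i factor as t(j,i) * t(i,k) whenever
# d(j,i) + d(i,k) = d(j,k). This shares no code path with the Brandes-style
# accumulation used by the package.

oracle_importance <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n); diag(D) <- 0
  Tc <- matrix(0, n, n)
  M <- adj
  for (len in seq_len(n - 1)) {
    newly <- D == Inf & M > 0
    D[newly] <- len
    Tc[newly] <- M[newly]
    M <- M %*% adj
  }
  diag(Tc) <- 1
  clos <- (n - 1) / rowSums(D)
  ut <- upper.tri(D)
  brid <- vapply(seq_len(n), function(i) {
    through <- outer(D[, i], D[i, ], "+") == D & is.finite(D)
    contrib <- outer(Tc[, i], Tc[i, ]) / ifelse(Tc > 0, Tc, 1) * through
    contrib[i, ] <- 0; contrib[, i] <- 0
    sum(contrib[ut])
  }, 0)
  clos * brid / (n * (n - 1) / 2)
}

# exhaustive upper-tail hypergeometric probability by direct combinatorial
# enumeration
oracle_hyper_p <- function(N, K, q, ov) {
  hi <- min(K, q)
  if (ov > hi) return(0)
  i <- ov:hi
  sum(choose(K, i) * choose(N - K, q - i)) / choose(N, q)
}

# exhaustive best coverage for each subset size, by direct combn enumeration
# (independent of the package's bitmask search)
oracle_best_coverage <- function(sets, universe) {
  m <- length(sets)
  vapply(seq_len(m), function(k) {
    combos <- utils::combn(m, k, simplify = FALSE)
    max(vapply(combos, function(ix) {
      length(intersect(unique(unlist(sets[ix])), universe))
    }, 0L))
  }, 0L)
}

# all connected labeled simple graphs on n nodes, as adjacency matrices
all_connected_adj <- function(n) {
  pairs <- utils::combn(n, 2)
  n_e <- ncol(pairs)
  out <- list()
  for (code in seq_len(2^n_e - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(n_e)]
    adj <- matrix(0, n, n)
    on <- which(bits == 1L)
    adj[cbind(pairs[1, on], pairs[2, on])] <- 1
    adj <- adj + t(adj)
    reach <- diag(n) + adj
    acc <- reach
    for (s in seq_len(n - 1)) acc <- acc %*% reach
    if (all(acc > 0)) out[[length(out) + 1L]] <- adj
  }
  out
}

# seeded random connected Erdos-Renyi graph with named vertices
rand_connected_graph <- function(n, p = 0.4) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) break
  }
  igraph::set_vertex_attr(g, "name", value = sprintf("n%02d", seq_len(n)))
}

graph_from_adj <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::set_vertex_attr(g, "name", value = sprintf("n%02d", seq_len(nrow(adj))))
}

# package scores aligned to vertex order of g, as a plain numeric vector
wi_of <- function(g) {
  sc <- importance_scores(g)
  sc$scores$wi[match(igraph::V(g)$name, sc$scores$id)]
}
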