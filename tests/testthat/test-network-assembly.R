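test_that("PPI merge collapses duplicates, drops self-loops, is order-independent", {
  net <- merge_ppi(list(data.frame(from = "A", to = "B"),
                        data.frame(from = "B", to = "A")))
  expect_equal(network_summary(net)$n_edges, 1L)

  net <- merge_ppi(list(data.frame(from = "A", to = "A")))
  expect_equal(network_summary(net)$n_nodes, 0L)  # loop-only node dropped

  l1 <- data.frame(from = c("A", "B"), to = c("B", "C"))
  l2 <- data.frame(from = "A", to = "B")
  net <- merge_ppi(list(l1, l2))
  expect_equal(network_summary(net)$n_edges, 2L)
  expect_equal(network_summary(net)$n_nodes, 3L)

  set.seed(7)
  lists <- replicate(4, data.frame(
    from = sample(LETTERS[1:8], 10, replace = TRUE),
    to = sample(LETTERS[1:8], 10, replace = TRUE)), simplify = FALSE)
  ref <- merge_ppi(lists)
  for (perm in list(c(2, 1, 4, 3), c(4, 3, 2, 1), c(3, 1, 4, 2))) {
    expect_true(network_equal(ref, merge_ppi(lists[perm])))
  }
})

test_that("disease network applies strict score filter, mapping and isolation removal", {
  ppi <- merge_ppi(list(data.frame(from = "X", to = "Z")))
  genes <- data.frame(symbol = c("X", "Y"), relevance_score = c(6, 4))
  expect_warning(net <- build_disease_network(ppi, genes), "isolated|maps")
  expect_equal(network_summary(net)$n_nodes, 0L)  # Y filtered, X isolated

  ppi <- merge_ppi(list(data.frame(from = "X", to = "Y")))
  net <- build_disease_network(ppi, data.frame(symbol = c("X", "Y"),
                                               relevance_score = c(6, 7)))
  nodes <- network_nodes(net)
  expect_equal(nodes$id, c("X", "Y"))
  expect_equal(nodes$weight, c(6, 7))
  expect_equal(unique(nodes$role), "disease_gene")
  expect_equal(network_summary(net)$n_edges, 1L)

  expect_warning(
    out <- build_disease_network(ppi, data.frame(symbol = c("X", "Y"),
                                                 relevance_score = c(5, 5))),
    "no disease gene")
  expect_equal(network_summary(out)$n_nodes, 0L)  # score == cutoff excluded
})

test_that("component-target network is a deduplicated bipartite graph", {
  ct <- build_ct_network(data.frame(component = c("c1", "c1", "c1"),
                                    target = c("A", "A", "B")))
  deg <- ct_degrees(ct)
  expect_equal(unname(deg$component["c1"]), 2L)

  ct <- build_ct_network(data.frame(component = c("c1", "c2", "c3"),
                                    target = "A"))
  expect_equal(unname(ct_degrees(ct)$target["A"]), 3L)

  empty <- build_ct_network(data.frame(component = character(),
                                       target = character()))
  expect_equal(network_summary(empty)$n_nodes, 0L)

  expect_error(build_ct_network(data.frame(component = c("c1", "A"),
                                           target = c("A", "B"))),
               "collide")
})

test_that("C-T-P union marks shared proteins and keeps PPI bridges", {
  ppi <- merge_ppi(list(data.frame(from = "A", to = "B")))
  dnodes <- network_nodes(ppi); dnodes$role <- "disease_gene"
  disease <- typed_network(dnodes, network_edges(ppi))
  ct <- build_ct_network(data.frame(component = "c1", target = "A"))

  ctp <- build_ctp_network(ct, disease, ppi)
  nodes <- network_nodes(ctp)
  expect_equal(network_summary(ctp)$n_nodes, 3L)
  expect_equal(network_summary(ctp)$n_edges, 2L)
  expect_equal(nodes$role[nodes$id == "A"], "target_and_disease_gene")

  # disjoint ct and disease components are both retained
  ppi2 <- merge_ppi(list(data.frame(from = c("A", "D"), to = c("B", "E"))))
  d2 <- build_disease_network(ppi2, data.frame(symbol = c("D", "E"),
                                               relevance_score = c(9, 8)))
  ct2 <- build_ct_network(data.frame(component = "c1", target = "A"))
  ctp2 <- build_ctp_network(ct2, d2, ppi2)
  g <- as_igraph(ctp2)
  expect_equal(igraph::components(g)$no, 2L)

  # a PPI edge between a target and a disease gene adds exactly one edge
  ppi3 <- merge_ppi(list(data.frame(from = c("A", "B"), to = c("B", "C"))))
  d3 <- build_disease_network(ppi3, data.frame(symbol = c("B", "C"),
                                               relevance_score = c(9, 8)))
  ct3 <- build_ct_network(data.frame(component = "c1", target = "A"))
  ctp3 <- build_ctp_network(ct3, d3, ppi3)
  expect_equal(network_summary(ctp3)$n_edges, 3L)  # c1-A, A-B, B-C
})

test_that("typed-network invariants hold after every builder", {
  set.seed(11)
  lists <- list(data.frame(from = sample(LETTERS[1:10], 15, replace = TRUE),
                           to = sample(LETTERS[1:10], 15, replace = TRUE)))
  ppi <- merge_ppi(lists)
  genes <- data.frame(symbol = LETTERS[1:10], relevance_score = runif(10, 0, 12))
  disease <- suppressWarnings(build_disease_network(ppi, genes))
  ct <- build_ct_network(data.frame(component = c("c1", "c1", "c2"),
                                    target = c("A", "B", "C")))
  ctp <- build_ctp_network(ct, disease, ppi)
  for (net in list(ppi, disease, ct, ctp)) {
    g <- as_igraph(net)
    expect_false(igraph::any_loop(g))
    expect_false(igraph::any_multiple(g))
    edges <- network_edges(net)
    comp_ids <- network_nodes(net)$id[network_nodes(net)$role == "component"]
    touching <- edges$relation != "component_target" &
      (edges$from %in% comp_ids | edges$to %in% comp_ids)
    expect_false(any(touching))
  }
  # node count bound for the union
  expect_lte(network_summary(ctp)$n_nodes,
             network_summary(ct)$n_nodes + network_summary(disease)$n_nodes)
})
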