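test_that("generators are pure functions of their configuration", {
  cfg <- synthetic_config(seed = 1, n_proteins = 60, ppi_attachment = 2,
                          n_disease = 25)
  expect_true(network_equal(generate_ppi(cfg), generate_ppi(cfg)))
  ppi <- generate_ppi(cfg)
  expect_identical(generate_disease_genes(cfg, ppi),
                   generate_disease_genes(cfg, ppi))
  a <- generate_components_and_targets(cfg, ppi)
  b <- generate_components_and_targets(cfg, ppi)
  expect_identical(a$associations, b$associations)
  expect_identical(as.data.frame(a$components), as.data.frame(b$components))
  fx1 <- make_planted_fixture(cfg)
  fx2 <- make_planted_fixture(cfg)
  expect_identical(fx1$truth, fx2$truth)
  expect_identical(fx1$associations, fx2$associations)
  # generators leave global random state untouched
  set.seed(99); before <- .Random.seed
  invisible(generate_ppi(cfg))
  expect_identical(before, .Random.seed)
})

test_that("the preferential-attachment layer has the closed-form edge count", {
  cfg <- synthetic_config(seed = 1, n_proteins = 50, ppi_attachment = 2)
  ppi <- generate_ppi(cfg)
  s <- network_summary(ppi)
  expect_equal(s$n_nodes, 50L)
  expect_equal(s$n_edges, (50 - 2) * 2)
  expect_equal(igraph::components(as_igraph(ppi))$no, 1L)

  cfg5 <- synthetic_config(seed = 4, n_proteins = 40, ppi_attachment = 5)
  expect_equal(network_summary(generate_ppi(cfg5))$n_edges, (40 - 5) * 5)
  expect_error(generate_ppi(synthetic_config(n_proteins = 3, ppi_attachment = 3)),
               "ppi_attachment")
})

test_that("ADME pass fractions are honored at the extremes and statistically", {
  ppi <- generate_ppi(synthetic_config(seed = 2, n_proteins = 60,
                                       ppi_attachment = 2))
  all_pass <- generate_components_and_targets(
    synthetic_config(seed = 2, n_proteins = 60, ppi_attachment = 2,
                     n_disease = 25, n_components = 40,
                     adme_pass_fraction = 1), ppi)
  expect_equal(nrow(filter_active_components(all_pass$components)), 40L)

  none_pass <- generate_components_and_targets(
    synthetic_config(seed = 2, n_proteins = 60, ppi_attachment = 2,
                     n_disease = 25, n_components = 40,
                     adme_pass_fraction = 0), ppi)
  expect_equal(nrow(filter_active_components(none_pass$components)), 0L)

  p <- 0.6
  big <- generate_components_and_targets(
    synthetic_config(seed = 3, n_proteins = 60, ppi_attachment = 2,
                     n_disease = 25, n_components = 1000,
                     adme_pass_fraction = p), ppi)
  rate <- nrow(filter_active_components(big$components)) / 1000
  se <- sqrt(p * (1 - p) / 1000)
  expect_lt(abs(rate - p), 3 * se)
})

test_that("component targets overlap disease genes at the configured rate", {
  cfg <- synthetic_config(seed = 6, n_proteins = 100, ppi_attachment = 2,
                          n_components = 200, n_disease = 30,
                          disease_overlap_fraction = 0.5,
                          targets_per_component = c(5L, 10L))
  ppi <- generate_ppi(cfg)
  dg <- generate_disease_genes(cfg, ppi)
  ct <- generate_components_and_targets(cfg, ppi, dg)
  frac <- mean(ct$associations$target %in% dg$symbol)
  # disease genes can also be hit by the background draw; the observed rate
  # sits a little above the configured fraction
  expect_gt(frac, 0.4)
  expect_lt(frac, 0.75)
  k <- table(ct$associations$component)
  expect_true(all(k <= 10))
})

test_that("the planted fixture encodes a recoverable unique ground truth", {
  cfg <- synthetic_config(seed = 8)
  fx <- make_planted_fixture(cfg)
  run <- run_formula_pipeline(fx$ppi_edge_lists, fx$disease_genes,
                              fx$components, fx$associations)
  expect_setequal(run$crn$effective_proteins, fx$truth$effective_proteins)
  m <- length(fx$truth$core_components)
  expect_setequal(run$selection$order[seq_len(m)], fx$truth$core_components)
  expect_equal(max(run$selection$cumulative_coverage[seq_len(m)]), 1)

  # disjoint tiles: cumulative coverage climbs by whole tiles to 1
  comp_targets <- split(fx$associations$target, fx$associations$component)
  sel <- tcc_select(comp_targets, fx$truth$effective_proteins)
  expect_setequal(sel$order, fx$truth$core_components)
  expect_equal(max(sel$cumulative_coverage), 1)

  # a decoy duplicating a planted tile never extends the cover
  dup <- comp_targets
  dup$ZDUP <- comp_targets[[fx$truth$core_components[1]]]
  sel2 <- tcc_select(dup, fx$truth$effective_proteins)
  expect_length(sel2$order, m)
  expect_equal(max(sel2$cumulative_coverage), 1)
})

test_that("generated tables survive a disk round trip through the readers", {
  cfg <- synthetic_config(seed = 9, n_proteins = 40, ppi_attachment = 2,
                          n_disease = 15, n_components = 10)
  ppi <- generate_ppi(cfg)
  dg <- generate_disease_genes(cfg, ppi)
  ct <- generate_components_and_targets(cfg, ppi, dg)

  f <- withr::local_tempfile()
  utils::write.table(network_edges(ppi)[, c("from", "to")], f, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  back <- merge_ppi(list(read_edge_list(f)))
  expect_true(network_equal(ppi, back))

  utils::write.table(ct$associations, f, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  expect_equal(read_associations(f), ct$associations,
               ignore_attr = "row.names")
})
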