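#' Run the full formula-optimization pipeline
#'
#' Chains every stage: merge the PPI edge lists, ADME-screen the components,
#' build the disease-gene, component-target and merged C-T-P networks, score
#' the C-T-P nodes with the composite importance measure, extract the
#' critical response network and its effective proteins, select components by
#' target coverage contribution, and (when an annotation collection is
#' supplied) run the enrichment validation against the baseline centrality
#' models.
#'
#' @param ppi_edge_lists list of edge-list data.frames (see
#'   [read_edge_list()]).
#' @param disease_genes data.frame `symbol`, `relevance_score`.
#' @param components a [component_records()] table.
#' @param associations data.frame `component`, `target`.
#' @param thresholds an [adme_thresholds()] list.
#' @param min_score strict relevance-score cutoff for disease genes.
#' @param collection optional [gene_set_collection()] for validation.
#' @param coverage_target coverage fraction defining the core active
#'   component group (default 1: full coverage of the effective proteins).
#' @param componentwise score a disconnected C-T-P network per component.
#' @param compare_methods methods for the model comparison when `collection`
#'   is given.
#' @return object of class `netpharm_run`: list with `ppi`, `active_components`,
#'   `disease_network`, `ct_network`, `ctp_network`, `scores`, `crn`,
#'   `categories`, `selection`, `cacg`, and optionally `validation`.
#' @export
run_formula_pipeline <- function(ppi_edge_lists, disease_genes, components,
                                 associations,
                                 thresholds = adme_thresholds(),
                                 min_score = 5,
                                 collection = NULL,
                                 coverage_target = 1,
                                 componentwise = FALSE,
                                 compare_methods = c("composite", "degree",
                                                     "betweenness", "clustering")) {
  ppi <- merge_ppi(ppi_edge_lists)
  active <- filter_active_components(components, thresholds)
  assoc <- associations[associations$component %in% active$id, , drop = FALSE]
  if (!nrow(assoc)) stop("no associations left after ADME screening")
  disease_net <- build_disease_network(ppi, disease_genes, min_score)
  ct <- build_ct_network(assoc)
  ctp <- build_ctp_network(ct, disease_net, ppi)

  scores <- importance_scores(ctp, componentwise = componentwise)
  crn <- extract_crn(ctp, scores)

  ctp_nodes <- network_nodes(ctp)
  prot_ids <- ctp_nodes$id[ctp_nodes$role != "component"]
  categories <- categorize_targets(
    ct_targets = intersect(unique(assoc$target), prot_ids),
    disease_genes = intersect(network_nodes(disease_net)$id, prot_ids),
    all_proteins = prot_ids
  )

  selection <- NULL; cacg <- NULL
  if (length(crn$effective_proteins)) {
    comp_targets <- split(assoc$target, assoc$component)
    selection <- tcc_select(comp_targets, crn$effective_proteins)
    cacg <- cacg_at(selection, coverage_target)
  }

  validation <- NULL
  if (!is.null(collection)) {
    validation <- compare_models(
      ctp, compare_methods, collection,
      disease_genes = intersect(network_nodes(disease_net)$id, prot_ids),
      target_genes = intersect(unique(assoc$target), prot_ids),
      componentwise = componentwise
    )
  }

  structure(list(
    ppi = ppi, active_components = active, disease_network = disease_net,
    ct_network = ct, ctp_network = ctp, scores = scores, crn = crn,
    categories = categories, selection = selection, cacg = cacg,
    validation = validation
  ), class = "netpharm_run")
}

#' @export
print.netpharm_run <- function(x, ...) {
  s <- network_summary(x$ctp_network)
  cat("netpharm_run\n")
  cat("  active components:", nrow(x$active_components), "\n")
  cat("  C-T-P network:", s$n_nodes, "nodes,", s$n_edges, "edges\n")
  cat("  effective proteins:", length(x$crn$effective_proteins),
      "(W_avg =", format(x$scores$w_avg), ")\n")
  if (!is.null(x$selection)) {
    cat("  TCC selection:", length(x$selection$order), "components, final coverage",
        sprintf("%.2f%%", 100 * max(c(0, x$selection$cumulative_coverage))), "\n")
    cat("  CACG:", length(x$cacg$components), "components",
        if (x$cacg$reached) "(coverage target reached)" else "(target unreached)", "\n")
  }
  if (!is.null(x$validation)) {
    cat("  model comparison:\n")
    print(x$validation)
  }
  invisible(x)
}
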