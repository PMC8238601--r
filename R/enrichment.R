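#' Gene-set collection
#'
#' Named gene sets (as read from GMT) with a background universe. Unless
#' supplied, the universe is the union of all genes in the collection.
#'
#' @param sets named list of character vectors (nonempty, unique names).
#' @param descriptions optional named character vector of set descriptions.
#' @param universe optional character vector; every set must be a subset.
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, universe = NULL) {
  if (!length(sets) || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("sets must be a nonempty named list")
  }
  if (anyDuplicated(names(sets))) stop("duplicate term ids in collection")
  sets <- lapply(sets, function(s) sort(unique(as.character(s))))
  if (any(lengths(sets) == 0L)) stop("every gene set must be nonempty")
  if (is.null(universe)) {
    universe <- sort(unique(unlist(sets, use.names = FALSE)))
  } else {
    universe <- sort(unique(as.character(universe)))
    stray <- setdiff(unlist(sets, use.names = FALSE), universe)
    if (length(stray)) {
      stop("gene(s) outside the supplied universe: ",
           paste(utils::head(stray, 5), collapse = ", "))
    }
  }
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(list(sets = sets, descriptions = descriptions, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x$sets), "sets over a universe of",
      length(x$universe), "genes\n")
  invisible(x)
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' Probability of drawing at least `overlap_count` genes of a set of
#' `set_size` when `query_size` genes are drawn without replacement from a
#' universe of `universe_size`. This is the p-value [enrich()] attaches to
#' every term (equivalently, a one-sided Fisher exact test, greater).
#'
#' @param overlap_count observed overlap.
#' @param set_size,universe_size,query_size hypergeometric margins.
#' @return numeric p-value in (0, 1].
#' @export
hypergeom_enrichment_p <- function(overlap_count, set_size, universe_size,
                                   query_size) {
  stats::phyper(overlap_count - 1, set_size, universe_size - set_size,
                query_size, lower.tail = FALSE)
}

#' Hypergeometric gene-set enrichment
#'
#' For each term, computes the upper-tail hypergeometric probability of
#' observing at least the actual overlap between the query (restricted to the
#' universe) and the term's gene set, drawing `query_size` genes from the
#' universe. Equivalent to a one-sided Fisher exact test (greater). Rows with
#' raw `p_value < alpha` are flagged enriched; Benjamini-Hochberg adjusted
#' p-values are reported alongside but do not gate the flag unless
#' `use_adjusted = TRUE`.
#'
#' @param query character vector of gene symbols; must intersect the universe.
#' @param collection a [gene_set_collection()].
#' @param alpha significance cutoff on the gating p-value (default 0.05).
#' @param use_adjusted gate the enriched flag on BH-adjusted p instead of raw.
#' @return data.frame sorted by p then term id: `term_id`, `description`,
#'   `overlap_count`, `query_size`, `set_size`, `universe_size`, `p_value`,
#'   `adjusted_p`, `enriched`.
#' @examples
#' gsc <- gene_set_collection(list(t1 = letters[1:5]), universe = letters[1:20])
#' enrich(letters[c(1:4, 10, 11)], gsc)  # p = 540/38760
#' @export
enrich <- function(query, collection, alpha = 0.05, use_adjusted = FALSE) {
  stopifnot(inherits(collection, "gene_set_collection"),
            alpha > 0, alpha < 1)
  query <- unique(as.character(query))
  q <- intersect(query, collection$universe)
  if (!length(q)) stop("query is disjoint from the collection universe")
  N <- length(collection$universe)
  rows <- lapply(names(collection$sets), function(id) {
    set <- collection$sets[[id]]
    K <- length(set)
    ov <- length(intersect(q, set))
    p <- hypergeom_enrichment_p(ov, K, N, length(q))
    data.frame(term_id = id, description = collection$descriptions[[id]],
               overlap_count = ov, query_size = length(q), set_size = K,
               universe_size = N, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  out$enriched <- (if (use_adjusted) out$adjusted_p else out$p_value) < alpha
  rownames(out) <- NULL
  out
}

#' Enriched term ids of an enrichment table
#' @param enrichment data.frame from [enrich()]
#' @return character vector of term ids flagged enriched.
#' @export
enriched_terms <- function(enrichment) {
  enrichment$term_id[enrichment$enriched]
}

#' Intervention terms
#'
#' Terms enriched both for the drug targets and for the pathogenic genes:
#' the exact intersection of the two enriched-term sets.
#'
#' @param targets_enriched,disease_enriched character vectors of term ids.
#' @return sorted character vector.
#' @export
intervention_terms <- function(targets_enriched, disease_enriched) {
  sort(intersect(unique(targets_enriched), unique(disease_enriched)))
}

#' Coverage of one term set by another
#'
#' Fraction of the denominator terms also present in the numerator terms.
#'
#' @param numerator,denominator character vectors of term ids; the
#'   denominator must be nonempty.
#' @return object of class `coverage_report`: list with `numerator_terms`,
#'   `denominator_terms`, `proportion`.
#' @export
coverage_proportion <- function(numerator, denominator) {
  numerator <- unique(as.character(numerator))
  denominator <- unique(as.character(denominator))
  if (!length(denominator)) stop("denominator term set is empty")
  structure(list(
    numerator_terms = sort(numerator),
    denominator_terms = sort(denominator),
    proportion = length(intersect(numerator, denominator)) / length(denominator)
  ), class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("coverage_report: %.2f%% (%d of %d terms)\n",
              100 * x$proportion,
              length(intersect(x$numerator_terms, x$denominator_terms)),
              length(x$denominator_terms)))
  invisible(x)
}

#' Compare node-importance models by functional coverage
#'
#' For each scoring method, extracts effective proteins from the network with
#' the strict above-mean rule, enriches them against the collection, and
#' reports what fraction of the intervention terms (terms enriched for both
#' the component targets and the pathogenic genes) the effective-protein
#' enrichment recovers. An empty effective set scores zero coverage.
#'
#' @param net the C-T-P `typed_network`.
#' @param methods subset of `c("composite", "degree", "betweenness", "clustering")`.
#' @param collection a [gene_set_collection()].
#' @param disease_genes,target_genes character vectors used to define the
#'   intervention terms.
#' @param alpha enrichment cutoff (default 0.05).
#' @param componentwise passed to [importance_scores()].
#' @return data.frame: `method`, `n_effective`, `n_enriched_terms`,
#'   `n_intervention_terms`, `coverage_percent`.
#' @export
compare_models <- function(net, methods, collection, disease_genes, target_genes,
                           alpha = 0.05, componentwise = FALSE) {
  ok <- c("composite", "degree", "betweenness", "clustering")
  if (!length(methods)) {
    return(data.frame(method = character(), n_effective = integer(),
                      n_enriched_terms = integer(),
                      n_intervention_terms = integer(),
                      coverage_percent = numeric(), stringsAsFactors = FALSE))
  }
  if (!all(methods %in% ok)) {
    stop("unknown method(s): ", paste(setdiff(methods, ok), collapse = ", "))
  }
  tgt_terms <- enriched_terms(enrich(target_genes, collection, alpha))
  dis_terms <- enriched_terms(enrich(disease_genes, collection, alpha))
  interv <- intervention_terms(tgt_terms, dis_terms)
  rows <- lapply(methods, function(m) {
    eff <- effective_proteins_by(net, m, componentwise = componentwise)
    eff_terms <- if (length(intersect(eff, collection$universe))) {
      enriched_terms(enrich(eff, collection, alpha))
    } else character()
    cov <- if (length(interv)) {
      coverage_proportion(eff_terms, interv)$proportion
    } else NA_real_
    data.frame(method = m, n_effective = length(eff),
               n_enriched_terms = length(eff_terms),
               n_intervention_terms = length(interv),
               coverage_percent = round(100 * cov, 2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
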