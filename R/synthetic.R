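# run code under a local RNG seed without touching global random state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic-data generators
#'
#' Bundles every knob of the seeded generators. Identical configurations
#' produce identical outputs; no generator touches global random state.
#'
#' @param seed integer seed.
#' @param n_proteins number of proteins in the scale-free PPI layer.
#' @param ppi_attachment edges added per new node in the
#'   preferential-attachment growth (the resulting edge count is
#'   `(n_proteins - ppi_attachment) * ppi_attachment`).
#' @param n_disease number of disease genes drawn from the PPI proteins.
#' @param relevance_meanlog,relevance_sdlog log-normal parameters of the
#'   relevance-score distribution (defaults put roughly a quarter of the mass
#'   below the customary cutoff of 5, so the score filter is exercised).
#' @param n_components number of chemical components.
#' @param adme_pass_fraction expected fraction of components whose ADME
#'   properties clear the screening thresholds.
#' @param targets_per_component integer range (min, max) of targets sampled
#'   per component.
#' @param disease_overlap_fraction probability that a sampled target is a
#'   disease gene rather than an arbitrary protein.
#' @param n_terms number of annotation gene sets.
#' @param term_size_range integer range (min, max) of genes per set.
#' @param planted_core_size number of core components in the planted fixture.
#' @param leaves_per_hub star size in the planted fixture topology.
#' @param n_background_genes,n_background_terms off-network genes and
#'   background sets added to the planted annotation collection.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_proteins = 300L, ppi_attachment = 3L,
                             n_disease = 80L,
                             relevance_meanlog = 2.2, relevance_sdlog = 0.8,
                             n_components = 20L, adme_pass_fraction = 0.6,
                             targets_per_component = c(3L, 15L),
                             disease_overlap_fraction = 0.4,
                             n_terms = 30L, term_size_range = c(5L, 40L),
                             planted_core_size = 5L, leaves_per_hub = 4L,
                             n_background_genes = 100L, n_background_terms = 15L) {
  cfg <- list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
              ppi_attachment = as.integer(ppi_attachment),
              n_disease = as.integer(n_disease),
              relevance_meanlog = relevance_meanlog,
              relevance_sdlog = relevance_sdlog,
              n_components = as.integer(n_components),
              adme_pass_fraction = adme_pass_fraction,
              targets_per_component = as.integer(targets_per_component),
              disease_overlap_fraction = disease_overlap_fraction,
              n_terms = as.integer(n_terms),
              term_size_range = as.integer(term_size_range),
              planted_core_size = as.integer(planted_core_size),
              leaves_per_hub = as.integer(leaves_per_hub),
              n_background_genes = as.integer(n_background_genes),
              n_background_terms = as.integer(n_background_terms))
  counts <- c(cfg$n_proteins, cfg$ppi_attachment, cfg$n_disease,
              cfg$n_components, cfg$n_terms, cfg$planted_core_size,
              cfg$leaves_per_hub)
  if (any(counts <= 0L)) stop("all counts must be positive")
  fr <- c(cfg$adme_pass_fraction, cfg$disease_overlap_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  structure(cfg, class = "synthetic_config")
}

#' Generate a scale-free synthetic PPI network
#'
#' Preferential-attachment growth: `ppi_attachment` seed nodes, the first
#' added node linking to all of them, every later node linking to
#' `ppi_attachment` distinct existing nodes chosen with probability
#' proportional to degree. The result is connected, simple, undirected, with
#' exactly `(n_proteins - ppi_attachment) * ppi_attachment` edges, and
#' deterministic under the seed.
#'
#' @param cfg a [synthetic_config()].
#' @return a `typed_network` of role-`target` proteins.
#' @export
generate_ppi <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- cfg$n_proteins; m <- cfg$ppi_attachment
  if (n < m + 1L) stop("need n_proteins >= ppi_attachment + 1")
  ids <- sprintf("PRT%04d", seq_len(n))
  with_seed(cfg$seed, {
    from <- integer((n - m) * m); to <- integer((n - m) * m)
    repeated <- integer(0)
    e <- 0L
    for (i in (m + 1L):n) {
      targets <- if (i == m + 1L) seq_len(m) else {
        picked <- integer(0)
        while (length(picked) < m) {
          t <- repeated[sample.int(length(repeated), 1L)]
          if (!(t %in% picked)) picked <- c(picked, t)
        }
        picked
      }
      for (t in targets) {
        e <- e + 1L
        from[e] <- i; to[e] <- t
      }
      repeated <- c(repeated, targets, rep.int(i, m))
    }
    edges <- data.frame(from = ids[from], to = ids[to], relation = "ppi",
                        stringsAsFactors = FALSE)
    typed_network(data.frame(id = ids, role = "target", stringsAsFactors = FALSE),
                  edges)
  })
}

#' Generate disease genes with relevance scores
#'
#' Samples `n_disease` proteins from the PPI network and attaches log-normal
#' relevance scores.
#'
#' @param cfg a [synthetic_config()].
#' @param ppi `typed_network` from [generate_ppi()].
#' @return data.frame with columns `symbol`, `relevance_score`.
#' @export
generate_disease_genes <- function(cfg, ppi) {
  stopifnot(inherits(cfg, "synthetic_config"))
  ids <- network_nodes(ppi)$id
  if (cfg$n_disease > length(ids)) stop("n_disease exceeds available proteins")
  with_seed(cfg$seed + 1L, {
    data.frame(
      symbol = sort(sample(ids, cfg$n_disease)),
      relevance_score = round(stats::rlnorm(cfg$n_disease,
                                            cfg$relevance_meanlog,
                                            cfg$relevance_sdlog), 2),
      stringsAsFactors = FALSE
    )
  })
}

# draw one ADME row; pass rows clear every threshold with margin, fail rows
# violate at least one property
draw_adme <- function(pass, th = adme_thresholds()) {
  if (pass) {
    c(mw = stats::runif(1, 200, th$mw - 20),
      ob = stats::runif(1, th$ob + 1, 80),
      caco2 = stats::runif(1, th$caco2 + 0.1, 1.5),
      dl = stats::runif(1, th$dl + 0.06, 0.8))
  } else {
    v <- c(mw = stats::runif(1, 200, th$mw - 20),
           ob = stats::runif(1, th$ob + 1, 80),
           caco2 = stats::runif(1, th$caco2 + 0.1, 1.5),
           dl = stats::runif(1, th$dl + 0.06, 0.8))
    bad <- which(stats::runif(4) < 0.5)
    if (!length(bad)) bad <- sample.int(4, 1)
    for (b in bad) {
      v[b] <- switch(names(v)[b],
                     mw = stats::runif(1, th$mw, 900),
                     ob = stats::runif(1, 0, th$ob),
                     caco2 = stats::runif(1, -2, th$caco2),
                     dl = stats::runif(1, 0, th$dl))
    }
    v
  }
}

HERB_CODES <- c("ZM", "XM", "HB", "BJT", "YYH", "DG")

# round-robin (circle-method) 1-factorization of pairs over x: consecutive
# pairs touch each element as evenly as possible
leaf_pair_schedule <- function(x) {
  k <- length(x)
  if (k < 2L) return(list())
  items <- if (k %% 2L == 1L) c(x, NA_character_) else x
  n <- length(items)
  out <- list()
  idx <- seq_len(n)
  for (round in seq_len(n - 1L)) {
    for (i in seq_len(n / 2L)) {
      a <- items[idx[i]]; b <- items[idx[n - i + 1L]]
      if (!is.na(a) && !is.na(b)) out[[length(out) + 1L]] <- c(a, b)
    }
    idx <- c(idx[1L], idx[n], idx[2L:(n - 1L)])  # rotate all but the first
  }
  out
}

#' Generate synthetic components and component-target associations
#'
#' ADME properties are drawn so each component independently clears all four
#' screening thresholds with probability `adme_pass_fraction`. Targets are
#' sampled per component from the PPI proteins, each drawn from the disease
#' genes with probability `disease_overlap_fraction`.
#'
#' @param cfg a [synthetic_config()].
#' @param ppi `typed_network` from [generate_ppi()].
#' @param disease_genes optional data.frame from [generate_disease_genes()];
#'   generated from `cfg` when omitted.
#' @return list with `components` (a [component_records()] table) and
#'   `associations` (data.frame `component`, `target`).
#' @export
generate_components_and_targets <- function(cfg, ppi, disease_genes = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (is.null(disease_genes)) disease_genes <- generate_disease_genes(cfg, ppi)
  proteins <- network_nodes(ppi)$id
  dg <- disease_genes$symbol
  n <- cfg$n_components
  rng <- cfg$targets_per_component
  with_seed(cfg$seed + 2L, {
    pass <- stats::runif(n) < cfg$adme_pass_fraction
    adme <- t(vapply(pass, draw_adme, numeric(4)))
    herbs <- vapply(seq_len(n), function(i) {
      paste(sort(sample(HERB_CODES, sample.int(3L, 1L))), collapse = ";")
    }, "")
    components <- component_records(data.frame(
      id = sprintf("CMP%03d", seq_len(n)),
      name = sprintf("component-%03d", seq_len(n)),
      herbs = herbs,
      mw = round(adme[, "mw"], 2), ob = round(adme[, "ob"], 2),
      caco2 = round(adme[, "caco2"], 3), dl = round(adme[, "dl"], 3),
      include_listed = FALSE, stringsAsFactors = FALSE
    ))
    assoc <- do.call(rbind, lapply(seq_len(n), function(i) {
      k <- sample(seq(rng[1], rng[2]), 1L)
      use_dg <- stats::runif(k) < cfg$disease_overlap_fraction & length(dg) > 0
      tgt <- character(k)
      tgt[use_dg] <- sample(dg, sum(use_dg), replace = TRUE)
      tgt[!use_dg] <- sample(proteins, sum(!use_dg), replace = TRUE)
      data.frame(component = sprintf("CMP%03d", i), target = unique(tgt),
                 stringsAsFactors = FALSE)
    }))
    list(components = components, associations = assoc)
  })
}

#' Generate an annotation gene-set collection
#'
#' Random sets over the PPI proteins, sized uniformly within
#' `term_size_range`.
#'
#' @param cfg a [synthetic_config()].
#' @param ppi `typed_network` from [generate_ppi()].
#' @return a [gene_set_collection()].
#' @export
generate_gene_sets <- function(cfg, ppi) {
  stopifnot(inherits(cfg, "synthetic_config"))
  proteins <- network_nodes(ppi)$id
  rng <- cfg$term_size_range
  with_seed(cfg$seed + 3L, {
    sets <- lapply(seq_len(cfg$n_terms), function(i) {
      sample(proteins, min(sample(seq(rng[1], rng[2]), 1L), length(proteins)))
    })
    names(sets) <- sprintf("TERM%03d", seq_len(cfg$n_terms))
    gene_set_collection(sets, universe = proteins)
  })
}

#' Planted-ground-truth fixture for end-to-end recovery tests
#'
#' Builds a complete input bundle whose pipeline output is known by
#' construction. The protein layer is a chain of stars: hub proteins, each
#' with `leaves_per_hub` leaf proteins, joined by degree-2 bridge proteins
#' (`hub - bridge - hub`). Hubs and bridges are cut vertices, so the
#' composite importance score provably ranks them above the network mean
#' while leaves score (near) zero: the designated effective-protein set is
#' exactly the hubs plus bridges. The planted core components tile that set
#' (component `j` targets hub `j` and bridge `j`; the last targets the final
#' hub alone), decoy components target only leaves, and annotation terms are
#' planted over the effective set (including bridge-only terms that a
#' degree-based model misses) on top of random background terms over leaves
#' and off-network genes.
#'
#' @param cfg a [synthetic_config()]; `planted_core_size` must not exceed
#'   `n_components`.
#' @return list with `ppi_edge_lists`, `disease_genes`, `components`,
#'   `associations`, `collection`, and `truth` (list: `effective_proteins`,
#'   `core_components`).
#' @export
make_planted_fixture <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  m <- cfg$planted_core_size
  if (m > cfg$n_components) stop("planted_core_size exceeds n_components")
  if (m < 2L) stop("planted fixture needs at least 2 core components")
  L <- cfg$leaves_per_hub
  hubs <- sprintf("HUB%02d", seq_len(m))
  bridges <- sprintf("BRG%02d", seq_len(m - 1L))
  leaves <- as.vector(outer(seq_len(L), seq_len(m),
                            function(l, h) sprintf("LEAF%02d_%02d", h, l)))
  effective <- c(hubs, bridges)
  proteins <- c(effective, leaves)

  # each hub carries a leaf clique (hub + leaves fully connected): leaf
  # degree and clustering are high while leaf bridging stays zero, so
  # degree/clustering baselines and the composite score genuinely disagree
  leaf_groups <- split(leaves, rep(seq_len(m), each = L))
  clique_edges <- do.call(rbind, lapply(leaf_groups, function(lv) {
    if (length(lv) < 2L) return(NULL)
    cmb <- utils::combn(lv, 2L)
    data.frame(from = cmb[1L, ], to = cmb[2L, ], stringsAsFactors = FALSE)
  }))
  edges <- rbind(
    data.frame(from = rep(hubs, each = L), to = leaves, stringsAsFactors = FALSE),
    clique_edges,
    data.frame(from = hubs[-m], to = bridges, stringsAsFactors = FALSE),
    data.frame(from = bridges, to = hubs[-1L], stringsAsFactors = FALSE)
  )

  core_ids <- sprintf("CORE%02d", seq_len(m))
  n_decoys <- cfg$n_components - m
  decoy_ids <- if (n_decoys > 0L) sprintf("DECOY%02d", seq_len(n_decoys)) else character()

  with_seed(cfg$seed + 4L, {
    disease <- data.frame(symbol = proteins,
                          relevance_score = round(stats::runif(length(proteins), 6, 40), 2),
                          stringsAsFactors = FALSE)

    # core component j covers the adjacent pair (hub j, bridge j); the tiles
    # are disjoint and cover the effective set exactly
    core_assoc <- do.call(rbind, lapply(seq_len(m), function(j) {
      tgt <- if (j < m) c(hubs[j], bridges[j]) else hubs[m]
      data.frame(component = core_ids[j], target = tgt, stringsAsFactors = FALSE)
    }))
    # decoys target a leaf pair of a single star, so they sit on the
    # periphery and cannot shortcut between stars; stars are filled
    # round-robin and leaf pairs follow a round-robin 1-factorization per
    # star so no leaf accumulates enough pass-through traffic to cross the
    # importance mean
    decoy_assoc <- if (n_decoys > 0L) {
      pair_queues <- lapply(leaf_groups, function(lv) {
        leaf_pair_schedule(sample(lv))
      })
      queue_pos <- integer(m)
      do.call(rbind, lapply(seq_len(n_decoys), function(j) {
        star <- ((j - 1L) %% m) + 1L
        q <- pair_queues[[star]]
        if (!length(q)) {
          tgt <- leaf_groups[[star]][1L]
        } else {
          pos <- (queue_pos[star] %% length(q)) + 1L
          queue_pos[star] <<- queue_pos[star] + 1L
          tgt <- q[[pos]]
        }
        data.frame(component = decoy_ids[j], target = unique(tgt),
                   stringsAsFactors = FALSE)
      }))
    } else NULL
    assoc <- rbind(core_assoc, decoy_assoc)

    n_all <- m + n_decoys
    adme <- t(vapply(rep(TRUE, n_all), draw_adme, numeric(4)))
    herbs <- vapply(seq_len(n_all), function(i) {
      paste(sort(sample(HERB_CODES, sample.int(3L, 1L))), collapse = ";")
    }, "")
    components <- component_records(data.frame(
      id = c(core_ids, decoy_ids),
      name = c(sprintf("core-component-%02d", seq_len(m)),
               if (n_decoys > 0L) sprintf("decoy-component-%02d", seq_len(n_decoys))),
      herbs = herbs,
      mw = round(adme[, "mw"], 2), ob = round(adme[, "ob"], 2),
      caco2 = round(adme[, "caco2"], 3), dl = round(adme[, "dl"], 3),
      include_listed = FALSE, stringsAsFactors = FALSE
    ))

    # planted terms: windows of 3 along the hub/bridge chain, plus bridge-only
    # terms invisible to a degree-based effective set, plus leaf/off-network
    # background terms
    chain <- as.vector(rbind(hubs, c(bridges, NA)))
    chain <- chain[!is.na(chain)]
    planted <- lapply(seq_len(length(chain) - 2L), function(i) chain[i:(i + 2L)])
    names(planted) <- sprintf("PLT%03d", seq_along(planted))
    if (length(bridges) >= 3L) {
      bset <- lapply(seq_len(length(bridges) - 2L), function(i) bridges[i:(i + 2L)])
      names(bset) <- sprintf("PLTB%02d", seq_along(bset))
      planted <- c(planted, bset)
    }
    bg_genes <- sprintf("BGG%03d", seq_len(cfg$n_background_genes))
    bg_pool <- c(leaves, bg_genes)
    bg <- lapply(seq_len(cfg$n_background_terms), function(i) {
      sample(bg_pool, min(max(3L, cfg$leaves_per_hub), length(bg_pool)))
    })
    names(bg) <- sprintf("BGT%03d", seq_along(bg))
    collection <- gene_set_collection(c(planted, bg),
                                      universe = c(proteins, bg_genes))

    list(
      ppi_edge_lists = list(edges),
      disease_genes = disease,
      components = components,
      associations = assoc,
      collection = collection,
      truth = list(effective_proteins = sort(effective),
                   core_components = core_ids)
    )
  })
}
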