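---
title: "Formula optimization with critical response networks and target coverage contribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Formula optimization with critical response networks and target coverage contribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Multi-herb formulas act through many chemical components hitting many
protein targets at once, and most of those components contribute little.
`netpharm` implements a network-based procedure for deciding which
components carry the therapeutic signal: assemble a
component-target-pathogenic (C-T-P) network, find the proteins that hold
that network together, and then pick the smallest group of components whose
targets cover those proteins.

```{r, message = FALSE}
library(netpharm)
```

## Network assembly

Three layers are merged:

* a **comprehensive PPI network** from one or more edge lists
  (`merge_ppi()`): duplicates collapse, self-loops are dropped, and gene
  symbols are trimmed and uppercased at ingest because public PPI sources
  disagree on case conventions;
* a **weighted disease-gene network** (`build_disease_network()`): disease
  genes with a relevance score *strictly* above a cutoff (default 5, in the
  units used by disease-gene databases) are mapped onto the PPI by exact
  symbol match, the subgraph is induced, and isolated nodes are removed.
  Scores become node weights but never enter any topological score;
* a **bipartite component-target network** (`build_ct_network()`) from a
  screened association table. Component identifiers live in their own
  namespace and are never case-folded, so they cannot collide with gene
  symbols (a collision is an error).

`build_ctp_network()` unions the three. Proteins appearing both as
component targets and as disease genes get the role
`target_and_disease_gene`. Which PPI edges enter is genuinely open: the
package adds *all* PPI edges among the included protein nodes (default
`ppi_edges = "all"`), because restricting to disease-network edges discards
bridges between the target layer and the disease layer that the importance
score is designed to detect; `ppi_edges = "disease_only"` is available for
sensitivity analysis.

## ADME screening

`filter_active_components()` keeps components with OB > 30 %, MW < 500 Da,
Caco-2 > 0.4 and DL > 0.14 — all four comparisons strict, matching the
printed form of these standard oral-activity criteria — unioned with an
`include_listed` flag for components admitted from the literature on
concentration grounds. The include-list is a set union, not a score
relaxation: a listed component is kept whatever its ADME profile. Records
with a missing ADME field fail closed unless listed, and the rejected ids
and reasons are attached to the result. `herb_overlap_counts()` partitions
components by their exact herb set (the quantity an UpSet plot displays), so
the bin counts always sum to the number of components.

## Composite node importance and the critical response network

For a simple undirected graph with $n \ge 3$ nodes, every node $i$ is scored

$$W_i \;=\; \underbrace{\frac{n-1}{\sum_k d(i,k)}}_{\text{closeness factor}}
\;\times\;
\underbrace{\frac{\sum_{j<k,\; j\neq i\neq k} t_{jk}(i)/t_{jk}}{n(n-1)/2}}_{\text{bridging factor}},$$

where $d(i,k)$ is the shortest-path distance, $t_{jk}$ the number of
shortest paths between $j$ and $k$, and $t_{jk}(i)$ the number passing
through $i$. The closeness factor measures how quickly the node reaches the
rest of the network; the bridging factor is the fraction of node pairs whose
communication routes through it. The bridging sum runs over **unordered**
pairs excluding the endpoints, matching the $n(n-1)/2$ normalization —
ordered pairs would silently double the numerator against a fixed
denominator. The graph is treated as undirected and unweighted: node
weights (relevance scores) and edge relations are deliberately ignored,
because the score is purely topological.

```{r}
p3 <- typed_network(data.frame(id = c("a", "b", "c"), role = "target"),
                    data.frame(from = c("a", "b"), to = c("b", "c")))
importance_scores(p3)$scores
```

The **critical response network** (`extract_crn()`) keeps exactly the nodes
with $W_i > W_{avg}$ — strictly above the mean. On a vertex-transitive
graph every score is equal and the CRN is empty; that is documented
behaviour, not an error. Kept non-component nodes are the **effective
proteins**. Degenerate inputs fail loudly: fewer than 3 nodes is an error
(the bridging normalization is undefined), and a disconnected graph is an
error unless `componentwise = TRUE`, in which case distances to unreachable
nodes leave the closeness denominator, unreachable pairs contribute zero to
bridging, and the bridging denominator stays the global $n(n-1)/2$. The
default is to refuse disconnected input because silently scoring components
separately changes the meaning of the mean threshold.

Baselines for comparison (`baseline_scores()`) are degree, unnormalized
betweenness and the local clustering coefficient (zero for degree < 2),
run through the same above-mean rule by `effective_proteins_by()`.

## Target coverage contribution

`tcc_select()` orders components by greedy maximum coverage of the
effective-protein universe: repeatedly pick the component covering the most
still-uncovered effective proteins, stop when no pick adds anything.
Components whose targets add nothing are never selected. Ties break by the
larger total effective-target count, then the lexicographically smaller id,
so selection is fully deterministic. The classical guarantee applies: at
every prefix length the greedy cover reaches at least $1 - 1/e$ of the
optimum, and greedy reaches 100 % exactly when the union of target sets
covers the universe. `mode = "exact"` enumerates all subsets (bitmask
search, capped at 20 components and a universe of 31) and reports the
optimal coverage for every subset size; it exists as a small-instance
oracle, not a production path. `cacg_at()` cuts the selection at a coverage
target — the core active component group is the shortest prefix reaching
full coverage of the effective proteins.

## Enrichment validation

`enrich()` attaches to every gene set the upper-tail hypergeometric
probability of the observed overlap (one-sided Fisher exact test). The
gate is the raw p-value at 0.05 by default; Benjamini-Hochberg adjusted
values are always reported and can gate instead (`use_adjusted = TRUE`),
but raw gating is the default to match the conventional cutoff in this
literature. The background universe defaults to the union of the loaded
collection because annotation files rarely state their background;
supplying an explicit universe is recommended whenever one is known.

**Intervention terms** are the terms enriched for both the component
targets and the disease genes. `compare_models()` scores the C-T-P network
with the composite measure and with each baseline, extracts each method's
effective proteins, and reports what fraction of the intervention terms
each effective set recovers — the package's operational definition of "the
selection kept the functionally relevant proteins".

## What the synthetic generators emulate

`generate_ppi()` grows a preferential-attachment graph
(`ppi_attachment` seed nodes; every later node links to that many distinct
existing nodes with probability proportional to degree), giving a
connected scale-free-like layer with exactly
$(n_{proteins} - m)\,m$ edges. Disease genes get log-normal relevance
scores (meanlog 2.2, sdlog 0.8), placing roughly a quarter of the mass
below the customary cutoff of 5 so the score filter is actually exercised.
ADME properties are drawn to pass all four thresholds with the configured
probability, with failing draws violating at least one property. These
choices reproduce orders of magnitude, not the marginal distributions of
any real database: passing tests on synthetic data demonstrates the
machinery is correct, not that any particular formula's screening outcome
is right.

`make_planted_fixture()` builds a ground-truth instance: hub proteins each
carrying a clique of leaves, joined in a chain by degree-2 bridge proteins.
Hubs and bridges are cut vertices, so the composite score provably ranks
them above the network mean, while leaves have zero bridging; the designed
effective set is exactly hubs plus bridges. Core components tile that set
with disjoint adjacent pairs; decoys target leaf pairs of a single star,
assigned round-robin over stars and over a 1-factorization of each star's
leaf pairs so no leaf accumulates enough pass-through traffic to cross the
mean. The leaf cliques make degree and clustering genuinely disagree with
the composite score (bridges sit below the mean degree; leaves have
clustering 1), and bridge-only annotation terms make that disagreement
visible in the enrichment comparison. Planted placement as cut vertices
makes recovery deterministic by construction rather than probabilistic.

## Problem sizes and numerical choices

* Score correctness is checked against an independent walk-counting oracle
  on every connected graph with 3-7 nodes (one representative per
  isomorphism class, 994 graphs) and 200 random connected graphs, at
  tolerance 1e-12.
* Greedy selection is checked against exhaustive subset enumeration on 500
  random instances of up to 12 components over up to 20 proteins.
* The hypergeometric tail is checked against direct combinatorial
  enumeration for every margin with universe up to 30.
* End-to-end recovery uses 100 seeded planted fixtures; the scale check
  runs one full pipeline on a ~1500-node / ~30000-edge synthetic C-T-P
  network, the size regime the method is intended for.
* All generators draw from an explicitly seeded local RNG and restore
  global random state; identical configurations give identical bytes.

## Limitations

* The importance score is defined for undirected, unweighted, simple
  graphs only; weighted or directed variants are out of scope.
* Symbol matching is exact after trim/uppercase; no alias resolution is
  attempted, so inputs mixing symbol conventions will silently under-merge.
* Enrichment treats gene sets as flat; ontology topology is ignored.
* Component selection optimizes coverage only — no dosage, toxicity or
  synergy weighting.
* Published headline counts from any specific study depend on database
  snapshots and supplementary tables; without those exact inputs the
  pipeline reproduces the procedure, not the printed numbers.
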