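# netpharm

Network-pharmacology formula optimization: given the protein targets of a
multi-component herbal formula and the pathogenic genes of a disease,
decide which components do the therapeutic work.

Multi-herb preparations contain hundreds of chemicals, most of them inert
at oral doses. `netpharm` implements a network procedure for isolating a
**core active component group (CACG)**:

1. **Assemble** a component-target-pathogenic (C-T-P) network from a merged
   protein-protein interaction (PPI) layer, a relevance-weighted
   disease-gene layer, and an ADME-screened component-target layer
   (OB > 30 %, MW < 500 Da, Caco-2 > 0.4, DL > 0.14, plus a literature
   include-list).
2. **Score** every node with a composite importance measure
   — the product of a closeness factor and a pair-normalized bridging
   factor:

   $$W_i = \frac{n-1}{\sum_k d(i,k)} \times
     \frac{\sum_{j<k,\ j\neq i\neq k} t_{jk}(i)/t_{jk}}{n(n-1)/2}$$

   where $d(i,k)$ is the shortest-path distance and $t_{jk}(i)/t_{jk}$ the
   fraction of shortest $j$–$k$ paths through $i$.
3. **Extract** the critical response network (CRN): the induced subgraph on
   nodes with $W_i$ strictly above the network mean. Its non-component
   nodes are the **effective proteins**.
4. **Select** components by target coverage contribution (TCC): greedy
   maximum coverage of the effective proteins with deterministic
   tie-breaking; the CACG is the shortest prefix reaching full coverage.
5. **Validate** by hypergeometric gene-set enrichment: the fraction of
   *intervention terms* (terms enriched for both targets and disease
   genes) recovered by each method's effective proteins, comparing the
   composite score against degree, betweenness and clustering baselines.

Inputs are plain TSV edge lists and tables plus GMT gene sets; outputs are
SIF networks (Cytoscape-ready), CSV tables and JSON summaries. Seeded
synthetic generators — including a planted-ground-truth fixture — produce
every input the pipeline reads.

## Worked example

```r
library(netpharm)

cfg <- synthetic_config(seed = 42)
fx  <- make_planted_fixture(cfg)     # inputs + known ground truth
run <- run_formula_pipeline(fx$ppi_edge_lists, fx$disease_genes,
                            fx$components, fx$associations,
                            collection = fx$collection)
run
#> netpharm_run
#>   active components: 20
#>   C-T-P network: 49 nodes, 97 edges
#>   effective proteins: 9 (W_avg = 0.02107331 )
#>   TCC selection: 5 components, final coverage 100.00%
#>   CACG: 5 components (coverage target reached)
#>   model comparison:
#>          method n_effective n_enriched_terms n_intervention_terms coverage_percent
#>   1   composite           9                9                    9              100
#>   2      degree          25                0                    9                0
#>   3 betweenness           9                9                    9              100
#>   4  clustering           0                0                    9                0
```

The fixture plants 9 effective proteins (hub and bridge cut vertices) tiled
by 5 core components among 15 decoys. The pipeline recovers exactly those
proteins, and the coverage curve climbs tile by tile to 100 %:

```r
coverage_curve(run$selection)
#>   rank component marginal cumulative_percent
#> 1    1    CORE01        2              22.22
#> 2    2    CORE02        2              44.44
#> 3    3    CORE03        2              66.67
#> 4    4    CORE04        2              88.89
#> 5    5    CORE05        1             100.00
```

The model-comparison table shows why the composite score exists: a
degree-based cut keeps high-degree clique members and misses the low-degree
bridges, recovering 0 % of the intervention terms here, while the composite
(and pure betweenness, on this topology) recovers all of them.

Real tables enter through `read_edge_list()`, `read_disease_genes()`,
`read_components()`, `read_associations()` and `read_gmt()`. A thin CLI
wrapping the same functions ships in `inst/cli/netpharm.R`
(`score`, `crn`, `select`, `simulate`).

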