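# brdnet

Topology and functional analysis of protein-family interaction
networks, built around the 42 human bromodomain-containing (BRD)
proteins — epigenetic readers of acetylated lysine that scaffold
multi-protein complexes.

## What it does

Given curated physical-interaction tables (BioGRID- and HIPPIE-style
dialects, or plain two-column edge lists), brdnet:

* merges them into a deduplicated undirected corpus and builds three
  networks: the **global PPIN**, the **family neighborhood PPIN**
  (family + direct interactors, induced subgraph), and the weighted
  **family–family PPIN** with self-loops;
* computes graph topology (density `2|E| / (|V|(|V|-1))`, radius,
  diameter, mean shortest path, clustering, compactness `E ≃ V^k`) and
  node statistics (degree, Brandes betweenness, closeness with the
  unreachable-pair penalty `|V|`, eccentricity, eigenvector centrality,
  local clustering, k-core number) — all implemented natively and
  cross-checked against igraph and brute-force oracles in the tests;
* classifies **hubs** (degree strictly above the mean) and compares the
  family against the rest by Wilcoxon rank-sum and 2×2 chi-square;
* fits a discrete **power law** to the degree distribution
  (Clauset-style MLE with KS-minimizing `xmin` and an analytic or
  bootstrap p-value);
* enumerates **cliques and maximal cliques** (Bron–Kerbosch) as protein
  complex proxies, and can rebuild a network from a published clique
  table for fixed-point validation;
* scores pairwise family similarity at exact shortest-path radii
  `s ∈ {1,2,3}`:
  `S_ij = |N_s(i) ∩ N_s(j)| / |N_s(i) ∪ N_s(j)|`, the radius-1 case
  being classic neighbor Jaccard;
* runs hypergeometric **gene-set enrichment** with BH-FDR over GMT
  collections, selects top pathways, builds per-protein
  pathway-involvement profiles and bipartite pathway sub-networks;
* generates complete **synthetic inputs** (scale-free networks with a
  planted high-degree family, dialect-faithful interaction files,
  gene-set collections with planted enrichment) so every stage is
  testable without downloads.

See `vignettes/brdnet-methods.Rmd` for the modelling choices and their
rationale.

## Worked example

Re-count the cliques of the published intra-family clique table and
inspect the reconstruction:

```r
library(brdnet)

cliques <- brd_reference_cliques()
net <- reconstruct_from_cliques(cliques)
net
#> <ppin> 30 nodes, 110 edges
length(maximal_cliques(net, min_size = 3)$cliques)
#> [1] 39
length(enumerate_cliques(net, min_size = 3)$cliques)
#> [1] 273

m <- node_metrics(net)
head(m[order(-m$degree), c("node", "degree", "betweenness", "core")], 5)
#>       node degree betweenness core
#> 8     BRD4     23   141.42814    6
#> 6     BRD2     16    48.65101    6
#> 22 SMARCA2     16    46.90775    6
#> 7     BRD3     13    14.25980    6
#> 23 SMARCA4     13    11.33407    6
```

The 39 maximal cliques are exactly the listed sets (the reconstruction
is a fixed point of the enumeration), 273 complete subgraphs of size
≥ 3 live inside them, and BRD4 is the most connected and most central
family member of the intra-family graph, sitting in its 6-core.

A single-hit pathway p-value at the whole-genome background (one of 42
family members inside a 32-gene set, background 23,467):

```r
round(hypergeometric_tail(23467, 32, 42, 1), 3)
#> [1] 0.056
```

End-to-end on synthetic data:

```r
spec <- synthetic_spec(n_nodes = 500, family_size = 10,
                       family_degree_boost = 2, n_sets = 20,
                       set_size_range = c(15, 60), seed = 11)
bundle <- generate_bundle(spec, "bundle_dir")
config <- pipeline_config(
  edge_files = list(list(path = bundle$edges, dialect = "hippie")),
  family_path = bundle$family, gmt_path = bundle$gmt,
  out_dir = "out_dir", background = 500, top_n_pathways = 10, seed = 11)
report <- run_pipeline(config)
#> [ingest] 1569 unique pairs (984 below 0.63 of 1569 scored)
#> [build] global 500/1569, family 116/244, family-family 0/0
#> [cliques] 0 maximal / 0 total (size >= 3)
#> [enrichment] 1/20 sets below FDR 0.05
report$hub_report$chi_square_p
#> [1] 3.723642e-08
report$enrichment$top_pathways[[1]]
#> [1] "SET001"
```

The planted 2×-degree family is detected as hub-enriched
(chi-square p ≈ 4e-08) and the planted gene set (`SET001`) is the one
set passing FDR < 0.05 — the pipeline recovers exactly what was planted
and nothing else. `out_dir/` holds `report.json` plus one TSV per
table (topology, node metrics, cliques, similarity matrices,
enrichment, involvement profile).

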