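---
title: "Methods: network topology and functional inference for protein families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network topology and functional inference for protein families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brdnet)
```

## Scope and model

brdnet studies a protein family — by default the 42 human
bromodomain-containing (BRD) proteins, epigenetic readers of acetylated
lysine — through the lens of the protein-protein interaction network
(PPIN): an undirected graph whose nodes are gene symbols and whose edges
are curated physical interactions. Three networks are derived from one
interaction corpus:

* the **global PPIN** over all proteins in the corpus (simple,
  unweighted);
* the **family neighborhood PPIN**: the subgraph induced on the family
  plus all its direct interactors, *including* interactor–interactor
  edges. The induced-closure reading is deliberate: the family
  neighborhood of a 42-member family reaches thousands of nodes and its
  edge count far exceeds the edges incident to the family itself, which
  only an induced subgraph can produce;
* the **family–family PPIN**: interactions with both partners in the
  family, weighted by evidence count (number of supporting publications
  or techniques) and keeping self-loops, which indicate homo-dimer or
  oligomer potential.

## Topology and node statistics

All graph statistics are computed natively on adjacency lists (igraph is
used in the test suite only, as an independent oracle):

* **density** uses the simple-graph formula $2|E|/(|V|(|V|-1))$ with
  self-loops excluded — the convention that reproduces a printed density
  of 0.182 for a 37-node, 121-edge family–family network;
* **radius, diameter, eccentricity** are computed on the largest
  connected component, and the **average shortest path** over connected
  pairs only, because real interactomes are disconnected yet report
  finite values for all of these;
* **compactness** follows the $E \simeq V^k$ rule: dense when
  $1 < k < 2$, sparse otherwise;
* **betweenness** uses Brandes' accumulation with unnormalized unordered
  pair counts and endpoints excluded;
* **closeness** is $1/\sum_j d(i,j)$ where an unreachable pair
  contributes distance $|V|$. This legacy penalty convention is chosen
  deliberately: on a disconnected interactome it keeps closeness finite
  and comparable across components, and it is the only convention
  consistent with mean closeness values of order $10^{-6}$ reported on
  graphs whose average path length is under 3;
* **eigenvector centrality** is obtained by power iteration on $A + I$
  (the shift suppresses period-2 oscillation on bipartite-ish graphs
  without changing eigenvectors), run to a $10^{-10}$ sup-norm tolerance
  from a uniform positive start — hence deterministic — and
  max-normalized so the top node scores 1;
* **local clustering** is triangles over $\binom{k}{2}$; nodes of degree
  < 2 have no defined coefficient and are excluded from the network
  average by default (a flag counts them as zero instead);
* **k-core numbers** come from iterative minimum-degree peeling.

**Hubs** are nodes with degree strictly above the network mean; the
family-vs-rest hub share is compared by a 2×2 Pearson chi-square. The
k-core threshold comparison (`group_threshold_chisquare`) takes the
threshold as a required argument with no default, because any such
cutoff is a study choice that cannot be recovered from the data.

## Degree-distribution fit

`fit_power_law` implements the discrete maximum-likelihood procedure of
Clauset–Shalizi–Newman: for each candidate lower cutoff `xmin` the
exponent maximizes the Hurwitz-zeta likelihood on the tail, and the
cutoff minimizing the Kolmogorov–Smirnov distance between empirical and
fitted tail CDFs is selected. Because both CDFs are step functions on
the integers, the KS sup is evaluated right-continuously at observed
atoms and against the fitted CDF just below each atom. The p-value is
analytic by default (asymptotic Kolmogorov distribution with Stephens'
small-sample correction); a Clauset-style semi-parametric bootstrap (100
replicates by default) is available behind a flag for users who prefer
the simulation route. Scanning starts at tails of at least 10
observations, and a fit is refused below 10 distinct degree values —
below that the "tail" is not meaningfully a distribution.

## Cliques as complex proxies

Maximal cliques (Bron–Kerbosch with pivoting, seeded in degeneracy
order) are the package's proxy for protein complexes; full clique
enumeration expands maximal cliques' subsets with deduplication. Output
is sorted members-within-cliques and cliques-lexicographically, making
results byte-stable; published clique tables carry no reproducible
order. `reconstruct_from_cliques` builds the union-of-within-set-edges
graph from a published clique table; running `maximal_cliques` on that
reconstruction must return exactly the listed sets (a fixed-point check,
encoded in the test suite). Any clique of size ≥ 3 lies inside triangles
and therefore inside some listed maximal clique, so the full size-≥3
clique census of the reconstruction is also preserved even though
triangle-free family edges are not recoverable from a clique list — this
equivalence is asserted, not assumed, in the tests.

## Neighborhood similarity at exact radii

For family members $i, j$, let $N_s(x)$ be the set of nodes at
shortest-path distance *exactly* $s$ from $x$ in the global network
("partners `s` steps away", not "within `s` steps"). The similarity at
radius $s$ is

$$S_{ij}(s) = \frac{|N_s(i) \cap N_s(j)|}{|N_s(i) \cup N_s(j)|},$$

with $i$ and $j$ removed from both sets first, and pairs with an empty
union scoring 0 so the matrix stays total. At $s = 1$ this is the
classic Jaccard similarity of direct-neighbor sets. Two readings of the
denominator "total number of neighbors of $i$ and $j$" are possible; the
sum of the two set sizes caps the score at 0.5 for any pair
($|A \cap B| \le \min(|A|,|B|) \le (|A|+|B|)/2$), which is incompatible
with most family pairs scoring above 0.5 at radii 2–3. The union reading
is therefore the default, and the sum variant is retained behind
`denominator = "sum"` so the cap is demonstrable rather than folklore.
Removing the focal pair keeps direct adjacency from inflating indirect
similarity; `include_focal = TRUE` restores the inclusive convention
used by generic Jaccard implementations.

Heatmap leaf orders come from average-linkage agglomerative clustering
(base `hclust`) after lexicographic pre-sorting of labels, which makes
tie-breaking deterministic; similarity matrices are converted to
distance as $1 - S$, and `Inf` sentinels in distance matrices are
replaced by one more than the largest finite entry.

## Statistics

The Wilcoxon rank-sum test, 2×2 Pearson chi-square, hypergeometric
upper tail and Benjamini–Hochberg step-up are implemented natively (base
R's versions are the reference oracles in the tests). The Wilcoxon test
enumerates all group assignments exactly when the combined sample is at
most 12 without ties — full enumeration is cheap there and exact —
switching to the tie-corrected, continuity-corrected normal
approximation above that. The chi-square applies no continuity
correction by default (Yates is a flag); a table with an empty margin
raises a typed degenerate-table condition instead of returning NaN. The
hypergeometric tail is summed in log space, stable at backgrounds of
order $2 \times 10^4$ genes.

## Enrichment

Gene-set enrichment is a hypergeometric over-representation test per
set, BH-corrected across the whole collection, with rows sorted by
(fdr, p, name). The default background is $N = 23{,}467$: the
long-standing whole-genome default of common enrichment tooling for
human symbols, and the value pinned to within ±100 by back-calculating
the published p-values for single-hit sets of sizes 32, 42 and 54 with
42 draws (that back-calculation is itself a test). The background is always an
explicit, overridable parameter, and synthetic collections declare
their own universe size. Involvement profiles count each family
protein's direct non-family interactors inside each selected pathway,
then row-normalize by that protein's total across the selected
pathways; zero rows are kept and flagged. Pathway sub-networks keep
only family-to-interactor edges, mirroring bipartite pathway diagrams,
and family members are excluded from the interactor side in both
profiles and sub-networks so a protein never counts toward its own
pathway involvement.

## Synthetic data: what it emulates and what it does not

`generate_network` grows a preferential-attachment graph (chosen over a
configuration model because the property the analyses need is a
power-law tail with a plausible KS p-value, which attachment delivers
without degree-sequence bookkeeping) and then plants the family: nodes
picked uniformly and wired to extra uniform partners until each reaches
`family_degree_boost` times the post-growth mean degree. Planting after
growth keeps the boost controllable independently of the exponent.
Defaults mirror the study conditions: 42 family members, a 50-set
collection with sizes 32–200 (the Hallmark range seen in the published
table), a 3× degree boost and 2,000 nodes for routine runs — network
sizes in tests (400–10,000 nodes) are the package's choice of desk
scale for each property being exercised, with the scale-free fit
checked at 10,000 nodes where the tail is informative. A
`synthetic_spec(n_nodes = 19843, m = 14)` call approximates the real
corpus's scale but is deliberately not part of the test suite.

Synthetic networks reproduce the heavy-tailed degree structure, a
dominant giant component and plantable hub/enrichment effects. They do
**not** reproduce: study bias (publication-count-correlated degrees),
evidence-count heterogeneity (synthetic confidences are a deterministic
hash, uniform-ish in [0,1], carrying no meaning), true community
structure, or correlated gene-set overlaps. Passing tests therefore
demonstrate algorithmic correctness and statistical calibration, not
biological validity on real corpora.

All generators are pure functions of (spec, seed): they save and
restore the caller's RNG state, and identical inputs produce
byte-identical files.

## Numerical and degenerate-input choices

* Symbols are upper-cased and whitespace-stripped everywhere; no alias
  resolution (none is derivable from the inputs). Malformed rows in
  interaction tables are counted and skipped, never fatal — large
  curated dumps routinely contain irregular rows.
* Records without a confidence score are never counted as "below
  threshold" and are never removed by the opt-in confidence filter; the
  default pipeline applies **no** confidence filtering, matching the
  practice of merging all evidence levels.
* Inter-source duplicate pairs keep the maximum confidence; duplicate
  rows within one source count as separate evidence items.
* Empty corpus → empty network (not an error); single-node network →
  distances reported as undefined; empty-margin 2×2 tables and
  all-identical degree samples raise typed errors rather than NaN.
* Unreachable distances use an `Inf` sentinel in matrices and the
  $|V|$ penalty inside closeness only.

## The pipeline

`run_pipeline` composes the stages in fixed order with per-stage
logging and failure attribution, writes one TSV per table analog plus a
single JSON report, and embeds the config in the report's provenance
block; the report body contains no timestamps, so identical inputs give
byte-identical reports. This package is a library first: the functions,
this vignette and `scripts/acceptance.R` are its interfaces, and no
shell entry point is shipped.

## Known limitations

* Pure-R graph routines target desk-scale networks (up to roughly
  $10^4$ nodes for degree-based analyses, $10^3$ for betweenness);
  reproducing every centrality on a 19,843-node corpus would want a
  compiled backend.
* The analytic KS p-value is asymptotic; for small tails the bootstrap
  flag is the safer choice.
* Eigenvector centrality on a disconnected graph concentrates on the
  dominant component, as with any power-method implementation.
* No identifier mapping: corpora using different symbol conventions
  must be harmonized upstream.
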