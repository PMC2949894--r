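---
title: "Stratifying conglomerate PPI networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratifying conglomerate PPI networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netstrat)
```

## The problem

Protein–protein interaction (PPI) databases pool interactions detected under
many different biological conditions into one static *conglomerate* network.
Analyses run on that union — hub and bottleneck identification, functional
enrichment, module extraction — implicitly assume the union reflects the
network operating in any one context. `netstrat` implements the machinery to
test that assumption: it overlays context-dependent protein lists (for
example tissue-resolved proteomics) on a conglomerate network, keeps the
interactions whose two partners are both present in a context (*induced
subnetwork stratification*), and quantifies how each analysis family changes
between the conglomerate and its stratified subnetworks.

Two features of the union drive the differences. First, percentile-defined
roles (hubs: top 20% of degree; bottlenecks: top 20% of betweenness) are
relative, so removing context-absent proteins re-ranks everything. Second,
the union can contain *artifact modules*: node sets that look densely
interconnected in the union although their members never co-occur in any
single context, so the apparent module exists in no real condition.

## The measures

**Node statistics.** Degree; betweenness as raw shortest-path pair counts
with fractional credit for tied shortest paths and endpoints excluded
(unnormalized — every percentile-based use is invariant to normalization);
local clustering coefficient with the degree-<2 convention of 0; and
eccentricity within each node's connected component (the only finite
convention on disconnected graphs). The network-level average eccentricity
averages the per-component values over all nodes.

**Roles and classes.** The hub threshold is the degree of the node at
descending rank `ceiling(pct/100 * N)`; every node at or above it is a hub,
so ties at the threshold all enter (the flagged set may exceed `pct`%; on a
regular graph it is everyone — documented degenerate case). Class
assignment applies the same inclusive rule at each cutoff of a scheme such
as 5/10/20/50 (five classes; alternate schemes are accepted), and a *leap*
is a shift of two or more classes between two networks, kept at two
regardless of the scheme. Status changes between a reference and a
comparison network are counted over nodes present in both; reference roles
missing from the comparison network are reported in a separate
`role_absent` column rather than being folded into demotions, because
absence and demotion are biologically different events. The promotion
percentage divides by the comparison network's role count; the demotion
percentage divides by the reference roles still present.

**Compatibility.** Node and edge agreement between two networks is the
Jaccard index over node sets and canonical unordered edge pairs. The index
of two empty sets is defined as 0 (with a warning) to avoid 0/0. The
randomized null builds `n_rep` (default 500) pairs of induced subnetworks
on uniform node samples of the two observed sizes — replicate *i* of one
size is paired with replicate *i* of the other — and the observed index is
compared against the replicate distribution with a two-sided one-sample
Student's t-test (the pairing and test form are recorded in the output
because they are conventions, not forced choices).

**Modularity and module extraction.** The partition quality score is

$$M = \sum_{s=1}^{N}\left[\frac{l_s}{L} - \left(\frac{k_s}{2L}\right)^2\right]$$

with `L` total edges, `l_s` intra-module edges and `k_s` the module's degree
sum; the one-module partition scores exactly 0. Three extraction algorithms
are provided. (1) *k-clique percolation*: communities are connected
components of the k-clique adjacency structure (cliques adjacent when they
share k−1 nodes), computed over maximal cliques of size ≥ k; communities
may overlap. (2) *Simulated-annealing modularity maximization*: Metropolis
acceptance over single-node reassignments plus collective merge/split
proposals, geometric cooling, best partition seen returned. Two numerical
choices matter and are easy to get wrong. Temperatures are measured in
units of `1/L` — the modularity change of moving one edge — because a
schedule quoted on the absolute scale (T0 = 1 down to 1e-3) never leaves
the random-walk regime on networks of realistic size. And split proposals
bisect a module by three sweeps of majority-neighbour reassignment inside
the module's own subgraph rather than uniformly at random: a uniform
bisection has essentially zero probability of cleaving a dense complex out
of a merged blob, which traps the annealer in coarse local optima. The
inner loop is compiled (Rcpp) and draws from R's RNG, so runs are exactly
reproducible under `set.seed`-style seeds. (3) *Edge-betweenness
partitioning*: repeatedly remove the single highest-edge-betweenness edge
(recomputing after every removal; ties broken by the lexicographically
smallest canonical edge ID) until a fraction of edges is gone; modules are
the non-singleton components of the residue — one-node components carry no
density and are not modules.

**Modular compatibility Cp.** For each module of one set, its best match in
the other set is the module sharing the most nodes, admissible only when
the shared nodes are at least 50% of the focal module's size; the
per-module term is the Jaccard-style ratio `C/(T+P−C)` of the matched pair
and unmatched modules contribute 0. A literal sum of these terms can exceed
1 as soon as module counts grow, contradicting the score's intended [0, 1]
range, so each direction's terms are averaged over its module count before
the two directions are averaged. This normalization restores `Cp(S,S) = 1`,
symmetry, and magnitudes comparable to reported values. Ties in matching
break by larger Jaccard with the focal module, then lexicographic module
ID, so results are deterministic. The comparison protocol contrasts (i) Cp
between total-network modules and each subnetwork's modules at matched
clustering parameters with (ii) Cp between module sets of the same network
across parameter settings, by a two-sided Mann–Whitney U test. For the
annealer, "different parameters" means different annealing seeds; for
clique percolation, different k; for edge-betweenness partitioning,
different removal fractions.

**Enrichment.** Over-representation is tested one-sided by the Fisher exact
(hypergeometric upper-tail) test at a default cutoff of 5e-4, without
multiple-testing correction by default (Benjamini–Hochberg q-values are
optional and reported alongside). The universe is the annotated proteins of
the background network; unannotated proteins leave both margins. Pair-level
enrichment counts an interacting pair once per annotation term its two
partners share, against the background network's annotated pairs.
Count-distribution comparisons use the chi-squared test of observed counts
against expectations proportional to a reference vector, pooling cells with
expected count below 1 into an "other" cell. The module-level summary
reports, per network, the fraction of modules with at least one enriched
term, the terms enriched in every network (universal), the terms enriched
in exactly one network (exclusive), and — among the conglomerate's
exclusive terms — candidate artifacts: functions over-represented only in
modules of the assembled union.

**Perturbation protocols.** Node-sampling nulls draw uniform samples
overlaid on the total network, accepted only when the induced subnetwork's
total degree is within 10% of the real subnetwork's. Uniform samples of the
exact list size often cannot reach the degree of a real, structure-rich
context list, so rejected draws adapt the sample size toward the degree
target (`s ← s·√(D_ref/D)`); every emitted replicate satisfies the 10%
window exactly, at whatever "similar number of proteins" was accepted —
node and edge counts of the nulls are close to, but not identical to, the
real networks'. The false-interaction protocol removes a fraction of edges
uniformly and adds the same number of uniformly drawn node pairs absent
from the original network, conserving node set and edge count exactly;
endpoints come from the existing node set so the stratification lists stay
applicable.

## The synthetic study generator

No external interactome or proteomics resource is downloaded; the generator
builds a study with planted ground truth. Its defaults are the study
conditions used throughout the package's validation: 1,000 proteins, a
4-level hierarchy (one total list; organs and cell culture at level 2; five
tissue lists at level 3; four refinements at level 4), four planted modules
per tissue, two artifact structures.

The conglomerate is a union of source layers, with per-edge provenance:

* a *backbone* layer — preferential attachment (m = 3) over the shared core
  plus the common pool, with core proteins entering the growth process
  first. This encodes two well-established facts at once: interaction
  databases are context-agnostic, and housekeeping proteins are both
  ubiquitous and disproportionately connected, so the hubs of the backbone
  are exactly the proteins every context retains.
* one sparse layer per context (preferential attachment, m = 1) over the
  proteins whose *home* context it is — each non-core protein is wired in
  only one context layer, so degree does not stack artificially on shared
  proteins.
* planted modules: near-clique complexes (internal density 0.8, sizes
  8–12) whose members are context-exclusive, wired to their context's
  background only through 3 interface edges. The density and the thin
  interface are not cosmetic: a complex whose members also carry ordinary
  background wiring is provably merged into larger communities by the
  modularity optimum (the resolution limit), and no optimizer could then
  recover it.
* artifact structures: a node set split into two halves living in contexts
  under *different* level-2 parents, completely cross-wired between the
  halves and with no within-half edges. Only the assembled union contains
  the whole dense structure; a lone half has no internal cohesion and
  dissolves into its context's background. Each artifact's annotation term
  also marks a few dozen scattered decoy proteins, as real terms do, so the
  term is enriched only where all carriers co-cluster — which happens in
  the union and nowhere else.

Context lists are the shared core plus samples grown by neighbourhood
snowballing from degree-biased seeds, emulating the abundance and
co-detection biases of proteomics; this is the feature that makes real
stratification behave differently from uniform node sampling in hub
preservation. List sizes are set so pairwise tissue-list Jaccard indices
fall in the 0.39–0.65 band; a configuration that cannot reach the band is
rejected with the feasible range. Planted edge counts are drawn as exact
counts (`round(p·n_pairs)` distinct pairs) rather than independent
coin-flips so that planted densities are deterministic and auditable.
Annotations mix housekeeping terms spread over the total list, one term per
planted module, artifact terms with decoys, a molecular-function category,
and 5% random noise assignments — enough noise to keep type-I simulations
honest without drowning the planted signal.

What the generator does *not* emulate: true experimental false-positive
structure (edges are exchangeable), protein abundance values, correlated
annotation hierarchies (terms are flat and pre-mapped), or the empirical
degree sequence of any particular organism. Passing tests therefore show
that the pipeline's logic recovers planted truth under realistic
assumptions, not that any particular biological dataset would behave
identically.

## Validation design and problem sizes

The test suite validates every computational primitive against independent
brute-force oracles (explicit shortest-path enumeration for node and edge
betweenness, direct k-subset clique enumeration, exhaustive set-partition
search for the annealing optimum, combinatorial tail sums for Fisher
p-values, all-pairs rank counting for the U statistic) on fixtures of up to
40 nodes, at 1e-10 where real-valued. The study-level checks run ten
independent synthetic families at the default 1,000-protein conditions and
verify four qualitative findings: total-vs-subnetwork modular compatibility
is lower than within-network compatibility across annealing seeds
(Mann–Whitney p < 0.05 on the pooled groups; typical means ≈ 0.2 vs ≈ 0.7);
hub demotion percentages under real stratification differ significantly
from degree-matched node-sampling nulls (Student's t on the pooled
ensemble); every planted artifact term is flagged as conglomerate-only
enriched; and at 10% replaced interactions the subnetwork-averaged hub
demotion percentage shifts by at most 5 percentage points (averaged over
families — the per-family average is the reporting unit because individual
subnetwork percentages carry binomial noise of comparable size at this
scale). Type-I control of the enrichment machinery is checked on
label-shuffled annotations over 1,000 repetitions; the attained rate sits
slightly below the nominal 0.05 because the hypergeometric test is
conservative under discreteness — at the margins used (universe 500,
carriers 100, foreground 100) the exact attained level is 0.037.

Annealing runs in these ensembles use a lighter schedule
(`moves_factor = 0.2`) than the single-network default; on the module
structures planted here the returned modularity is insensitive to further
budget and the schedule is part of the recorded parameters.

## A worked run

```{r example, eval = FALSE}
bundle <- paper_shaped_fixture(seed = 1)      # ~300 proteins, 5 tissues
fam <- stratify_all(bundle$conglomerate, bundle$hierarchy)
fam

st_total <- node_stats(fam$networks$total)
hubs <- identify_roles(st_total, "degree", pct = 20)
status_change(hubs, identify_roles(node_stats(fam$networks$tissue1),
                                   "degree", 20))

cp_comparison_protocol(fam, "sa", list(1L, 2L, 3L),
                       sa_control = list(moves_factor = 0.3))
```

The full pipeline, including the randomized nulls and the perturbation
stage, is one call:

```{r pipeline, eval = FALSE}
cfg <- run_config(synth = synth_config(seed = 1), out_dir = "run1")
res <- run_pipeline(cfg)
res          # per-analysis transferability verdicts
summary(res)
```

## Known limitations

* Cp's directional means weight every module equally regardless of size; a
  size-weighted variant would emphasize large modules differently.
* The annealer optimizes plain Newman–Girvan modularity and inherits its
  resolution limit; complexes below the limit are only recovered because
  the generator wires them accordingly. On real data a resolution-aware
  objective could behave differently.
* Betweenness-based quantities are exact but quadratic in network size;
  the package targets networks of up to a few tens of thousands of edges.
* The adaptive sample-size rule in the node-sampling null changes the
  nominal sample size to honor the degree window; where both cannot hold
  simultaneously the degree window wins, and the accepted size is recorded
  on the returned object.
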