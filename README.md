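# netstrat

Context-dependent stratification of conglomerate protein–protein
interaction (PPI) networks, and a quantitative answer to the question: *how
much of a standard network analysis survives when the static union of all
known interactions is restricted to the proteins actually present in one
tissue or condition?*

PPI databases pool interactions detected under many conditions into one
static **conglomerate** network. `netstrat` overlays context-dependent
protein lists (e.g. tissue-resolved proteomics) on that union and keeps the
interactions whose two partners are both present — the induced subnetwork
of each context — then compares conglomerate and subnetworks across four
analysis families:

- **Topology** — degree, betweenness, clustering coefficient, eccentricity;
  hubs (top 20% of degree, inclusive ties) and bottlenecks (top 20% of
  betweenness); status changes (`hub → non-hub`, `non-hub → hub`, absence);
  degree/betweenness class assignment (top 5/10/20/50% bands) with *leap*
  changes (|Δclass| ≥ 2); Welch/Student/Mann–Whitney distribution tests.
- **Compatibility** — node and edge agreement between network pairs by the
  Jaccard index `J = |A∩B| / |A∪B|`, with a 500-replicate randomized
  node-sampling null.
- **Modules** — k-clique percolation, simulated-annealing maximization of
  the modularity `M = Σ_s [l_s/L − (k_s/2L)²]` (compiled inner loop), and
  edge-betweenness partitioning with a removal-fraction cutoff; agreement
  between module sets by the bidirectional modular compatibility score
  `Cp ∈ [0,1]` (best-match overlap with a 50% coverage rule), contrasted
  between networks and within a network across clustering parameters by a
  Mann–Whitney U test.
- **Enrichment** — one-sided Fisher exact tests per annotation term at the
  protein, interacting-pair and module level (default α = 5e-4), χ²
  comparisons of annotation-count distributions, and detection of
  *conglomerate-only* enriched module terms — candidate artifacts of
  assembling a union whose members never co-occur in one context.

Two perturbation protocols support the inference: degree-constrained random
node-sampling subnetworks (total degree within 10% of the mimicked real
subnetwork) and false-interaction replacement (a fraction of edges swapped
for uniformly drawn absent pairs, conserving |V| and |E| exactly). A
synthetic study generator with planted ground truth (scale-free backbone,
context-exclusive complexes, union-only artifact structures, housekeeping
and context-specific annotations) makes the entire pipeline testable with
no external downloads.

## Worked example

```r
library(netstrat)

bundle <- paper_shaped_fixture(seed = 1)   # ~300 proteins, 5 tissue contexts
fam <- stratify_all(bundle$conglomerate, bundle$hierarchy)
fam
#> <stratified_family> 12 context networks (total: 'total')
#>   L1 total            267 nodes   1013 edges  coverage 0.964
#>   L2 organs           240 nodes    894 edges  coverage 0.941
#>   L2 cell_culture      82 nodes    194 edges  coverage 0.872
#>   L3 tissue1          117 nodes    395 edges  coverage 0.886
#>   ...

st <- node_stats(fam$networks$total)
hubs <- identify_roles(st, "degree", pct = 20)
status_change(hubs, identify_roles(node_stats(fam$networks$tissue1),
                                   "degree", 20))
#> <status_change> total vs tissue1 (degree)
#>   role->nonrole 8 (23.5%)  nonrole->role 0 (0.0%)  role absent 48

cp_comparison_protocol(fam, "sa", list(1L, 2L, 3L),
                       sa_control = list(moves_factor = 0.3))
#> <cp_report> sa: mean Cp total-vs-subnetwork 0.294, within-network 0.698
#>   Mann-Whitney U = 0, p = 1.15e-06
```

Reading: of the total network's hubs that survive into the tissue
subnetwork, about a quarter stop being hubs (48 more are absent from the
tissue altogether), and the modules found in the total network agree far
less with any tissue's modules (mean Cp ≈ 0.29) than two clusterings of
the *same* network agree with each other (≈ 0.70) — module analysis on the
union does not transfer to contexts.

The full comparative study — statistics, roles, classes, compatibility with
nulls, modules, enrichment, and the perturbation stages — is one call,
ending in a per-analysis transferability verdict table:

```r
res <- run_pipeline(run_config(synth = synth_config(seed = 1)))
res
#> <netstrat_run> transferability of conglomerate-network analyses:
#>         analysis          verdict
#>       statistics not transferable
#>             hubs   to some degree
#>         non-hubs     transferable
#>      bottlenecks   to some degree
#>  non-bottlenecks     transferable
#>    compatibility not transferable
#>       enrichment not transferable
#>          modules not transferable
#>                                                                   evidence
#>                                                   14/15 Welch tests p<0.01
#>                                                   mean role->nonrole 22.8%
#>  mean nonrole->role 17.8% of subnetwork roles, 2.7% of reference non-roles
#>                                                   mean role->nonrole 30.5%
#>  mean nonrole->role 23.6% of subnetwork roles, 2.7% of reference non-roles
#>                                               mean J_v 0.479 vs null 0.280
#>                          5/5 chi2 p<0.01; 0 context-exclusive module terms
#>                             Cp 0.259 between vs 0.482 within, MW p=1.2e-06
```

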