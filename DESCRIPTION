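Package: netstrat
Title: Stratification of Conglomerate Protein-Protein Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assemble a conglomerate protein-protein interaction
    network from multiple interaction datasets, stratify it into
    context-dependent subnetworks from leveled protein lists, and quantify
    how topological roles (hubs, bottlenecks, degree/betweenness classes),
    node and edge agreement (Jaccard compatibility with randomized nulls),
    functional enrichment (Fisher exact tests on proteins, interacting
    pairs and modules; chi-squared distribution comparisons) and modular
    structure (k-clique percolation, simulated-annealing modularity
    maximization, edge-betweenness partitioning, and a bidirectional
    modular compatibility score) differ between the conglomerate network
    and its stratified subnetworks. Includes degree-constrained node
    sampling and edge-replacement perturbation protocols, and a synthetic
    study generator with planted modules and conglomerate-only artifact
    structures for validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
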