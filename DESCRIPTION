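Package: netprox
Title: Network Proximity and Functional Similarity Between Drug-Target and Disease Gene Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical machinery for linking a compound's predicted protein
    targets to a disease gene set on a protein-protein interaction network:
    the inter-subnetwork average shortest-path proximity statistic with
    permutation Z-scores and empirical p-values, Gene Ontology
    biological-process profile construction with graph-based (Wang-style)
    term semantic similarity aggregated by best-match average, Fisher's
    exact pathway over-representation, and a better-or-close binding
    affinity classification of putative docking targets. Includes seeded
    synthetic generators (scale-free networks, planted-proximity gene sets,
    GO-like ontologies with annotations, pathway collections, docking
    tables) so the whole pipeline is testable without external downloads,
    plus readers and writers for the standard interchange formats
    (edge lists, SIF, OBO 1.2, GAF 2.x, GMT, CSV).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
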