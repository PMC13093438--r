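Package: phylodisc
Title: Gene-Tree Discordance, Coalescent Simulation and Hybridization
    Detection for Phylogenomic Species Complexes
Version: 0.1.0
Authors@R:
    person("phylodisc", "developers", email = "phylodisc@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for the discordance-analysis core of
    transcriptome-scale species delimitation studies: single-copy ortholog
    filtering (occupancy, organellar screening, column trimming, length
    classes, average-bootstrap-support filtering, long-branch flagging,
    supermatrix concatenation), multispecies-coalescent (MSC) and
    network-MSC gene-tree simulation, GTR+Gamma sequence simulation,
    PhyParts-style per-node concordance accounting, empirical-versus-
    simulated tree-distance comparison for incomplete-lineage-sorting
    assessment, cyto-nuclear conflict attribution, and invariants-based
    hybridization detection with inheritance-probability (gamma)
    estimation and a null-simulation false-positive filter. A synthetic
    scenario generator makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape (>= 5.0),
    phangorn,
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
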