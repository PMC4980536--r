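Package: dtprofiler
Title: System-Profile Druggability Analysis and Drug-Target Interaction
    Networks for Kinase Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative analysis of established (approved-drug) and
    clinical-trial kinase targets. Implements Smith-Waterman local
    alignment with Karlin-Altschul E-value statistics and similarity-level
    classification; per-target system profiles (similar proteins outside
    the family, affiliated pathways, tissue distribution) with
    druggability compliance rules, cohort summaries and median-trend
    comparison; a 3-of-4-profile promising-target rule evaluated against
    tabulated development outcomes; bipartite drug-target interaction
    networks with degree analysis, ICD disease-class subnetworks and
    Cytoscape-compatible export; and a synthetic-data generator for
    cohorts, sequence families and degree-prescribed bipartite networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    grDevices,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
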