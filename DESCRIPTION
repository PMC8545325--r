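Package: chronomiR
Title: Longitudinal miRNA-mRNA Integration and Network Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrates per-time-point differential expression results for
    microRNAs and mRNAs into small, pathway-focused regulatory networks.
    Provides per-time-point hypergeometric pathway overrepresentation
    analysis, fuzzy c-means soft clustering of pathway trajectories,
    correlation- and target-database-filtered miRNA-mRNA interaction
    networks for a chosen pathway, longitudinal pair statistics
    (cross-correlation, spline trajectories, regression prediction,
    odds ratios with Wald confidence intervals), and export to
    PathVisio data files and Cytoscape-compatible GraphML/SIF. A seeded
    synthetic-fixture generator with recorded planted truth supports
    fully offline testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
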