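Package: pcitrif
Title: Partial-Correlation Networks and Regulatory Impact Factors with
    Breeding-Value Nodes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers putative regulators of quantitative phenotypes from
    transcriptome data by combining partial-correlation network inference
    (PCIT) with the regulatory impact factor (RIF) statistic, treating
    genomic estimated breeding values (GEBVs) as first-class network nodes.
    Provides low-expression filtering, PCIT in gene+miRNA+trait and
    miRNA+trait modes, GEBV-targeted RIF1/RIF2 with per-trait and
    PCA-score-based contrast groups, attribute-annotated association
    networks with hub detection, a seeded synthetic-data generator with
    recorded ground truth, and an end-to-end pipeline with a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
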