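Package: phytonet
Title: Tripartite Plant-Compound-Gene Networks and Multi-Method Enrichment
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated network-pharmacology analysis of plant-compound-gene
    relationship tables: validated ingestion and cleaning of relationship CSVs,
    construction of typed tripartite networks with topology and centrality
    profiling, Louvain community detection with degree-preserving
    configuration-model significance testing, and three enrichment engines
    (hypergeometric over-representation analysis, preranked gene set enrichment
    analysis, and gene set variation analysis) with per-compound and per-plant
    enrichment streams, publication-quality figures, and a hierarchical,
    fully reproducible output tree.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    data.table,
    jsonlite,
    xml2,
    yaml,
    ggplot2,
    Rcpp,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
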