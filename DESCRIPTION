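Package: sepnet
Title: Immune Gene Co-Expression Network Analysis for Sepsis Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and compares immune gene co-expression networks from
    whole-blood expression profiles of sepsis patients and healthy controls.
    Provides gene-to-immune-category annotation from KEGG/GO/Reactome style
    gene sets with majority-vote tie rules, per-gene differential expression
    (Welch t, Benjamini-Hochberg FDR) and a GAGE-style gene set enrichment
    statistic, Spearman-threshold network construction, the full panel of
    network topology metrics (clustering coefficient, density, heterogeneity,
    centralization, path statistics, degree assortativity, modularity),
    detection of prominent isolated functional clusters, percent-difference
    comparison of network parameters between conditions, and a synthetic
    block-correlation expression simulator so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    limma,
    stats,
    utils,
    yaml
Suggests:
    fgsea,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
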