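Package: screentriage
Title: Hit Identification Triage for High-Throughput Kinase Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end, tested pipeline for prospective hit identification
    in high-throughput screening (HTS) campaigns: per-plate normalization of
    raw fluorescence against DMSO/staurosporine controls with Z-prime quality
    control, threshold-based hit calling, Tanimoto-graph Louvain clustering
    of hits with maximum-common-substructure scaffolds and ligand-efficiency
    diversification, joint-replicate four-parameter logistic dose-response
    fitting with IC50 capping and activity classification, virtual-screening
    ranking evaluation via hit and scaffold discovery-rate curves,
    pose-ensemble and stereoisomer score aggregation policies, and a
    continuous pharmacophore subset-matching score. A synthetic-data
    generator emulating a 46,743-compound IRAK1 kinase screen provides every
    input, so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    minpack.lm,
    stats,
    utils
Suggests:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
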