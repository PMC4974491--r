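Package: ascnet
Title: Temporal Coexpression Network Analysis of Antibody-Secreting Cell
    Differentiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Weighted gene-coexpression analysis of time-course expression
    data from plasmablast to plasma-cell differentiation under cytokine
    (interferon) stimulation. Provides detection-based probe filtering,
    quantile normalization, moderated t differential expression with
    Benjamini-Hochberg correction, soft-thresholded adjacency and
    topological overlap networks with dynamic dendrogram cutting and
    eigengene-based module merging, cross-condition module matching by
    Fisher exact overlap, trend-split hypergeometric signature enrichment
    with ontology propagation, and differential intramodular connectivity
    ("rewiring") statistics. Includes a synthetic time-course generator
    that emulates the three-condition, eight-time-point, three-donor
    study design so the full pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    limma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
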