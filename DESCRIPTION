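Package: funcnet
Title: Functional Gene Network Integration and Expression Meta-Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Standardizes heterogeneous gene expression matrices and
    interaction networks onto a shared gene namespace, normalizes and imputes
    expression data (per-gene z-scores, distance-weighted k-nearest-neighbour
    imputation), builds co-expression networks, integrates co-expression,
    physical and regulatory evidence by averaging z-score edge weights,
    extracts high-confidence subgraphs around query gene sets, and runs
    random-effects differential-expression meta-analysis (REML or
    DerSimonian-Laird) with Benjamini-Hochberg false-discovery control and
    permutation gene-set enrichment. A nested key-value metadata model with
    curated overrides, MD5 provenance logging and a checksum-driven
    incremental pipeline make every analysis reproducible; seeded synthetic
    fixture generators with planted ground truth make every stage testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    broom,
    dplyr,
    fgsea,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    igraph,
    metafor,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
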