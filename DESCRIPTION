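Package: altpath
Title: Alternatively-Activated Pathway Analysis from Binary Gene Activity Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies differentially-activated genes and pathways between two
    sample groups from microarray detection (present/marginal/absent) calls,
    classifies gene-pair activity-alteration patterns, learns condition-specific
    directed gene networks by greedy equivalence search over binary activity
    data, expands pathway gene sets through network neighborhoods, and builds an
    FDR-controlled pathway-crosstalk network. Includes a synthetic-data
    generator with known ground truth, a robustness analysis for group
    imbalance, tidy accessors for all result types, and Cytoscape-compatible
    network export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
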