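Package: personet
Title: Multi-Omic Network Integration for Personality Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline linking variably transcribed genes to
    personality-associated genomic networks. Provides fuzzy non-negative
    matrix factorization biclustering of expression profiles, permutation
    tests for brain-region colocalization of gene sets against an
    expression atlas, construction and greedy minimization of multi-layer
    interaction networks (protein-protein, TF-gene, miRNA-gene) from seed
    genes, detection of shared regulatory hubs, hub expansion into a
    multi-modular regulatory network with regulator-signature modules and
    network analytics, and contingency-table enrichment statistics for
    liquid-liquid phase separation annotations. Includes a synthetic-data
    generator that emulates the statistical structure of every input so
    the full pipeline is testable without restricted data.
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
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
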