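Package: tissuetalk
Title: Network-Based Discovery of Inter-Tissue Crosstalk from Multi-Tissue
    Differential Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds tissue-specific core protein networks from differential
    proteomics (seed expansion over a directed regulatory background followed
    by per-component Steiner minimal tree simplification, validated against
    random seed resamplings by a |Z| criterion), assembles a directed
    secreted-protein ligand/receptor interface between tissues with upstream
    and downstream differential regulatory context and a low-expression
    exclusion filter, and quantifies the interface functionally through
    hypergeometric pathway over-representation with Benjamini-Hochberg
    correction, metabolic-pathway proportions, and a one-sample z-test
    against the background pathway composition. Includes a synthetic-data
    generator that plants differential proteins and crosstalk axes so the
    whole pipeline is testable without external databases.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
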