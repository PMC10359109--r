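Package: ctsea
Title: Cell-Type-Specific Enrichment Analysis of Gene Lists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives tissue-cell-type signature gene panels from annotated
    single-cell RNA-seq count matrices (log2 CPM normalization, one-vs-rest
    t-statistics, top-fraction signature selection), tests query gene lists
    for cell-type-specific over-representation with a one-sided
    hypergeometric test, and adjusts raw enrichment p-values by ranking them
    against a precomputed reference of trait-associated gene sets, with a
    cumulative length factor, a cross-cell-type rank p-value, and Fisher's
    method to combine the two. Includes a synthetic-data generator with
    planted cell-type markers for end-to-end validation, GMT/TSV input and
    output, broom-style tidiers, ggplot2 visualisations, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    fgsea,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
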