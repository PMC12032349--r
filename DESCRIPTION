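Package: microseasons
Title: Seasonal and Interannual Succession Analysis for Marine
    Metagenomic Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing multi-year coastal ocean metagenomic
    time series: consensus contig taxonomy, coverage-table
    normalisation and rare-feature filtering, decomposition of each
    taxon or gene family into monthly (seasonal) and yearly
    (interannual) anomalies, PCA and multi-table co-inertia ordination,
    distance-based PERMANOVA variance partitioning, community
    aggregated biogeochemical traits (Fe/N/P stress, carbon
    degradation), average genome size estimation from single-copy
    marker genes, and an annotation keyword screen. Includes a
    synthetic seasonal/ENSO community simulator with known ground
    truth so every stage is verifiable without external data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
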