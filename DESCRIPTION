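Package: guildnet
Title: Co-Occurrence Networks and Temporal Dynamics for r/K
    Selection-Switch Microbiome Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers signed co-occurrence networks from microbial abundance
    time series using noise-injected similarity measures and the ReBoot
    bootstrap/permutation significance procedure with Benjamini-Yekutieli
    q-values, detects guild-like modules with the walktrap algorithm,
    decomposes network edges over time with per-day z-scores, and provides
    community-level ordination (Bray-Curtis PCoA) and sequential PERMANOVA.
    Includes a synthetic microcosm generator that plants r- and K-strategist
    guilds under a crossover selection-regime switch so the whole pipeline
    can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
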