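Package: befmix
Title: Biodiversity-Ecosystem Functioning Analysis for Synthetic Microbial Consortia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for combinatorial biodiversity experiments with defined
    bacterial consortia: two-level fractional factorial community designs with
    alias diagnostics, phylogenetic diversity metrics (Faith's PD, mean
    pairwise distance) on UPGMA or user-supplied rooted trees, trait-based
    functional diversity (FDis and dendrogram FD) from electron-equivalent
    normalised metabolic fingerprints, ecosystem-function responses (soluble
    COD removal efficiency, biomass proxies), transgressive and
    non-transgressive overyielding log response ratios with richness-level
    tests, diversity-function regressions, and a main-effects t-ratio screen.
    Includes calibrated and mechanistic synthetic-data generators so the whole
    pipeline runs end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
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
    withr
Suggests:
    optparse,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
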