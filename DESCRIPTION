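Package: phylorisk
Title: Phylogenetic and Taxonomic Selectivity of Plant Extinction Risk
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing the distribution of IUCN extinction risk
    across a flora's taxonomy and phylogeny. Builds dated supertrees by
    grafting unplaced species onto a taxonomy-labelled backbone and
    interpolating node ages (BLADJ-style), measures phylogenetic signal in
    binary threat status with the Fritz-Purvis D statistic against shuffle
    and Brownian-threshold nulls, tests taxonomic selectivity by family
    randomization, quantifies within-category community structure (NRI/NTI
    under a phylogeny-pool null), compares time-varying Mk2 models of risk
    evolution (delta, linear-change, two-rate, constant) by AIC, and fits
    AICc-ranked log-log regressions of threatened-species richness on
    elevation and climate. Includes seeded generators for synthetic trees,
    risk tables and forest-block tables so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    picante,
    phytools,
    withr,
    knitr
Config/testthat/edition: 3
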