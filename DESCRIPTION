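Package: lbgwin
Title: Detectability of Latitudinal Biodiversity Gradients Under
    Heterogeneous Fossil Sampling Windows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation framework for testing whether latitudinal
    biodiversity gradients (LBGs) of known shape (flat, unimodal or
    bimodal) remain detectable in the shallow-marine fossil record after
    filtering occurrences through the heterogeneous spatial sampling
    window of fossil collections. Provides a 56-stage Permian-Neogene
    chronostratigraphic scaffold, synthetic stage-level palaeogeographies
    on a 1 degree grid, virtual-species occurrence simulation on weighted
    probability grids with distance-decay placement, sampling windows
    built from Paleobiology Database style collection tables or a
    synthetic generator, spatial sampling metrics (spatial sampling
    coverage and summed minimum-spanning-tree length), classical
    rarefaction with an analytic hypergeometric oracle, proportional
    latitudinal richness curves, and curve-comparison statistics
    (total displacement, Pearson correlation, Kolmogorov-Smirnov tests,
    peak bin and zone detection, coefficients of determination and
    rank-sum contrasts), orchestrated by a reproducible experiment
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    geosphere,
    jsonlite
Config/testthat/edition: 3
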