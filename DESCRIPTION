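Package: defaunacarbon
Title: Defaunation Impacts on Tropical Forest Above-Ground Carbon
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate the consequences of losing large-bodied
    frugivorous seed dispersers for above-ground carbon storage in tropical
    forest census plots. Classifies tree species by seed-disperser group,
    computes per-stem above-ground biomass from a moist-forest allometry
    with wood specific gravity imputation, and runs a zero-sum stochastic
    removal-replacement simulation stratified by diameter class, across
    defaunation scenarios and intensities, with bootstrap confidence
    intervals. Includes a synthetic forest-census generator so the full
    pipeline is testable without plot-network data access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite
Config/testthat/edition: 3
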