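Package: divehab
Title: Dive Classification, Space Use and Habitat Suitability for
    Central-Place Foraging Seabirds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for processing seabird biologging data from GPS loggers
    with time-depth recorders: dive detection from 1-Hz depth traces,
    dive-metric computation and U/V shape classification, association of
    dives with foraging GPS locations, breeding-phase segmentation from
    dive-shape phenology, chi-square contingency analysis of dive shape by
    year, kernel density utilization distributions with isopleth extraction,
    and presence/pseudo-absence habitat suitability modelling with binomial
    generalized additive models, small-sample AIC all-subsets selection and
    daily environmental prediction. Includes a central-place foraging
    simulator with known habitat truth so every pipeline stage can be
    validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    geosphere,
    jsonlite,
    mgcv,
    stats,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
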