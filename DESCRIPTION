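Package: ecoskill
Title: Skill Assessment for End-to-End Ecosystem Model Output
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify how well an ecosystem model reproduces
    observed system state. Computes a suite of seven skill metrics
    (average error, average absolute error, root mean squared error,
    modeling efficiency, and Spearman, Pearson and Kendall correlation)
    on paired observed/modeled annual time series of species biomass,
    fishery landings and derived ecosystem indicators; expands
    stratified trawl-survey catch rates to swept-area biomass estimates
    with confidence bands; derives 22 standard ecosystem indicators
    from biomass, landings and primary-production series; compares
    hindcast against forecast skill with an empirical quantile
    classification; and analyses metric redundancy by principal
    component analysis. A synthetic-ecosystem generator with known
    ground truth and configurable model-skill levels makes every stage
    of the pipeline testable without survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
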