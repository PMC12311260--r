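Package: fenflux
Title: Chamber-Flux Greenhouse Gas Budgets and Emission Factors for Fen Paludicultures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end pipeline for deriving annual greenhouse gas budgets
    and water-table-stratified emission factors from closed-chamber flux
    measurements on rewetted organic soils. Computes areal CO2, CH4 and N2O
    fluxes from chamber concentration series, partitions net ecosystem exchange
    into ecosystem respiration (Lloyd-Taylor) and gross primary production
    (rectangular hyperbola) with campaign-based parameter interpolation,
    integrates annual trace-gas balances, assembles net ecosystem carbon
    balances and CO2-equivalent budgets under AR4/AR5 global warming
    potentials, aggregates water-table-class emission factors with IPCC
    off-site defaults, and fits nonlinear water-table response models
    (penalized cubic regression splines, Tweedie and square-root-link GLMs)
    to extract mitigation-optimal water tables and carbon-sink thresholds.
    Includes a synthetic fen-site generator with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    mgcv,
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
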