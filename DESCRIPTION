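Package: evcog
Title: Cost-of-Goods Modelling and Technology Selection for Extracellular
    Vesicle Manufacturing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Decision-support model for planning scalable manufacture of
    extracellular vesicles (EVs). Computes annual cost of goods (consumables,
    labor, amortized equipment) for every combination of a cell-expansion
    technology (planar vessels, microcarrier single-use bioreactors,
    hollow-fiber devices) and an EV-harvest technology (ultracentrifugation,
    precipitation, size-exclusion chromatography, ultrafiltration), applies
    feasibility constraints (facility space limits, a minimum 24-h culture
    lag, a lots-per-year window), and identifies the cheapest pair for any
    lot size and annual demand. Includes exponential-growth EV-accumulation
    kinetics with parameter fitting from time-course data, one-at-a-time
    cost-parameter sensitivity sweeps, biological-scenario comparison, and
    clinical dose-capacity arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
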