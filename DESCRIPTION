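Package: profitmax
Title: Profit-Maximisation Stomatal Optimisation Coupled to a Multilayer
    Soil Water Store for Species-Level Drought Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates species-level plant water relations during drought
    with an instantaneous gain-risk (profit-maximisation) stomatal scheme:
    carbon gain from Farquhar C3 photosynthesis is weighed each timestep
    against a hydraulic cost derived from a Weibull xylem vulnerability
    curve. The optimiser is coupled to a multilayer soil water store with
    Campbell retention and root-conductance-weighted water uptake, driven
    by sub-daily meteorology. Ships a hydraulic and photosynthetic trait
    registry for 15 south-eastern Australian eucalypt species, a synthetic
    meteorological forcing generator with drought scenarios, the 6-month
    Standardised Precipitation Index, and scenario engines for rainfall
    reduction, CO2 enrichment and leaf-area sensitivity experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
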