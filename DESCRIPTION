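Package: wheatDA
Title: Winter Wheat Yield Estimation by Ensemble Kalman Filter Data Assimilation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates regional winter wheat yield by assimilating remotely
    sensed leaf area index (LAI) and surface soil moisture into a daily
    crop-growth and soil-water model with a stochastic ensemble Kalman filter.
    Provides a reduced-order wheat growth simulator, optical (NDVI/NDWI) and
    SAR (water cloud model) retrieval operators, three assimilation strategies
    (LAI only, soil moisture only, joint), stage-weighted yield regressions
    fitted separately for irrigated and rain-fed areas, decision-tree wheat
    masking with a terrain-based irrigated/rain-fed split, and a synthetic
    scene generator for end-to-end twin experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, yaml
Suggests: testthat (>= 3.0.0), jsonlite, optparse, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
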