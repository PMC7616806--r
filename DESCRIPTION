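Package: climind
Title: Climate-Sensitive Health Indicators from Gridded Climate and Population Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes a suite of climate-sensitive health indicators from daily
    gridded climate fields and gridded, age-stratified population counts:
    percentile-threshold heatwave detection and person-days of exposure,
    wet-bulb-globe-temperature heat-stress risk hours and sectoral labour
    capacity loss, heat-attributable mortality and its monetisation, the
    standardised precipitation-evapotranspiration drought index (SPEI) with
    log-logistic L-moment calibration, growing-degree-day crop season lengths,
    temperature-dependent basic reproduction numbers for Aedes-borne
    arboviruses, threshold-based malaria and coastal Vibrio suitability, a
    fixed-effects panel regression linking growing-season heatwave days to
    food-insecurity prevalence, urban greenness and low-elevation population
    overlays, and net carbon-price accounting. A seeded synthetic-data
    generator emulates the statistical structure of reanalysis-scale inputs
    (seasonality, secular warming, autocorrelated daily noise, heterogeneous
    population) so the full pipeline runs and is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
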