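Package: barleygap
Title: Soil-Water-Crop-Nitrogen Simulation and Yield-Gap Analysis for
    Spring Barley on Marginal Sandy Soils
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A one-dimensional agroecosystem simulator and analysis toolkit
    for quantifying yield potential, water- and nitrogen-limited yield gaps,
    nitrate leaching and water/nitrogen use efficiencies of spring barley on
    sandy (Arenosol) soils.  Couples a mass-conservative Richards-equation
    soil water solver with van Genuchten-Mualem hydraulics, FAO-56
    Penman-Monteith reference evapotranspiration, thermal-time crop phenology
    with radiation-use-efficiency growth and Feddes root water uptake, and a
    layered soil mineral-nitrogen balance with convective nitrate transport.
    Includes a Shuffled Complex Evolution (SCE-UA) global optimizer with a
    two-stage calibration protocol (phenology, then per-horizon saturated
    conductivity), a seeded synthetic weather generator for three contrasting
    season archetypes, stress-switch yield-gap decomposition, and nitrogen
    fertilization-rate sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
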