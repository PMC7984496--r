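Package: apbidose
Title: Dosimetry of Interstitial Multicatheter Breast Brachytherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the dosimetric analysis of accelerated partial breast
    irradiation (APBI) delivered by interstitial multicatheter high-dose-rate
    (HDR) Ir-192 brachytherapy. Implements the AAPM TG-43 dose-calculation
    formalism for line and point sources, free-hand one- and two-plane implant
    geometry, voxelized breast/phantom anatomy including the quadrilateral
    skin-region construction, dwell-time optimization with coverage
    normalization, dose-volume-histogram plan-quality indices (CI, COIN, DHI,
    DNR, OI, D95) and clinical constraint checking, a photon Monte Carlo that
    quantifies the backscatter deficit at tissue-air interfaces (the mechanism
    behind treatment-planning-system skin-dose overestimation), and a synthetic
    patient-cohort generator with emulated radiochromic-film skin measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pracma,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
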