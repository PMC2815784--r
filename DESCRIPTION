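Package: interbeam
Title: Dosimetry and Planning for Interlaced Synchrotron Microbeam Radiosurgery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the dosimetry of spatially fractionated synchrotron
    microbeam radiosurgery in water phantoms. Builds and calibrates a
    filtered wiggler-like photon spectrum, runs Monte Carlo coupled
    photon-electron transport of a single planar microbeam through a
    cylindrical water phantom (compiled core), composes microbeam-array and
    multi-port interlaced dose profiles by superposition, evaluates
    peak-to-valley dose ratios, interlacement enhancement, depth attenuation
    and lateral penumbra, back-plans entrance doses for a prescribed target
    dose, and emulates radiochromic-film dose images for geometric
    verification. Includes analytic single-beam kernels with closed-form
    array sums that serve as exact oracles for the superposition machinery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tiff
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
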