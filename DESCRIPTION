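Package: soilplsda
Title: Soil Type Recognition from NIR Spectra by PLS Discriminant Analysis
    with Genetic-Algorithm Wavelength Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies soil types from near-infrared diffuse reflectance
    spectra. Implements PLS2 regression on class-indicator responses (PLSDA)
    with a maximum-predicted-value assignment rule, leave-one-out
    cross-validation, variable importance in projection (VIP) scores,
    genetic-algorithm wavelength selection driven by a calibration plus
    cross-validation fitness, and a resampling experiment comparing fixed
    versus re-selected wavelength subsets. Includes a synthetic spectra
    generator with class-specific absorption bands for fully reproducible
    testing, and CSV readers/writers for wide-format spectra tables.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, yaml, Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
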