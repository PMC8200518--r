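Package: irtg43mc
Title: Monte Carlo TG-43 Dosimetry for an HDR Ir-192 Brachytherapy Source
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the Varian GammaMed Plus high-dose-rate Ir-192
    brachytherapy source as nested finite cylinders, transports its photon
    spectrum through water and air phantoms with an analog Monte Carlo engine
    (free-electron Klein-Nishina incoherent scattering, Thomson-sampled
    coherent scattering, photoelectric absorption) combined with a
    deterministic first-flight estimator, and extracts the TG-43 dosimetry
    parameters: air-kerma strength per unit activity, dose-rate constant,
    radial dose function with its fifth-order polynomial fit, and the 2D
    anisotropy function.  Ships emission-spectrum and photon-interaction
    fixtures, verification oracles, and comparison tools against published
    reference datasets.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
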