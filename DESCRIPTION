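Package: hairspec
Title: Spectral Analysis of Longitudinal Hair Cortisol and HPA-Axis Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal hair cortisol measured in
    consecutive hair segments: per-individual exponential decline correction,
    discrete Fourier amplitude spectra with a shuffled-segment null model and
    bootstrap standard errors, cosinor correction for seasonality, and
    stochastic simulators of the hypothalamus-pituitary-adrenal (HPA) axis
    with and without gland-mass dynamics whose simulated output feeds the
    identical pipeline. Includes a synthetic cohort generator emulating the
    statistical structure of real hair-cortisol data, so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
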