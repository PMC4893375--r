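Package: mcti
Title: Tissue Oxygenation and Blood Volume Estimation from Multispectral
    Images by Inverse Monte Carlo and Random Forest Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates tissue oxygenation and blood volume fraction from
    multispectral reflectance images. Labeled reflectance spectra are
    generated with a multi-layered Monte Carlo photon-transport model of
    hemoglobin-perfused tissue, adapted to a camera's spectral bands,
    normalized to cancel illumination changes, and used to train random
    forest regressors that are applied per pixel to image stacks. Includes
    the modified Beer-Lambert linear estimator as a training-free baseline,
    support vector and k-nearest-neighbor comparators, an in-silico
    robustness experiment suite (noise sweeps, domain switch, sample-size
    curves), and a synthetic phantom generator for end-to-end testing of
    the imaging path.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    ranger,
    e1071,
    caret,
    parallel,
    stats,
    utils,
    yaml,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
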