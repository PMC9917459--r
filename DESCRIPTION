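Package: quantalfluor
Title: Optical Quantal Analysis of Glutamate-Sensor Fluorescence Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for estimating quantal parameters of glutamatergic
    neurotransmission from fluorescence recordings of genetically encoded
    glutamate sensors. Provides a synthetic-data generator with known
    ground-truth release statistics (binomial or Poisson multivesicular
    release, additive noise, baseline drift, rundown, Gaussian spot
    footprints), tile-based detection of responsive regions in movies,
    background-corrected dF/F trace extraction, asymmetric least squares
    baseline subtraction, wavelet peak detection with template-locked
    amplitude extraction, coefficient-of-variation release-probability
    analysis across calcium conditions, and per-region quantal histogram
    fitting under binomial and Poisson release models with
    Kolmogorov-Smirnov model assessment and brute-force selection of the
    number of release sites.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    rlang,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
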