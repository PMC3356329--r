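Package: beatmech
Title: Mechanobiology of Beating Cardiomyocytes from AFM Force Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for atomic force microscopy (AFM) recordings of
    spontaneously beating stem-cell-derived cardiomyocytes. Converts cantilever
    deflection trajectories into contraction force, detects individual beats and
    quantifies their force, duration (FWHM) and rate, calibrates cantilever
    spring constants by the thermal-noise (equipartition) method, fits Hertz
    contact-mechanics models to indentation curves to obtain Young's modulus and
    local cell height, and assembles grid "dwell maps" pairing local elasticity
    with local contraction force. A statistical layer provides nonparametric
    bootstrap confidence intervals, Mann-Whitney tests, the two-sample
    two-dimensional Kolmogorov-Smirnov (Fasano-Franceschini) test for comparing
    joint (force, modulus) point clouds, and Hill-equation EC50 estimation for
    inotropic dose-response series. A seeded synthetic-data module emulates the
    instrument so that every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
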