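Package: oilshelf
Title: Shelf-Life Chemometrics for Edible Oils by NIR Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring oxidative degradation of edible oils
    (hempseed oil in particular) from near-infrared spectra collected over
    a storage-time x temperature x packaging-material factorial design.
    Provides a synthetic-data generator emulating oil oxidation kinetics
    and NIR-like spectra with known ground truth, spectral preprocessing
    (saturation masking, baseline correction, mean centering),
    ANOVA-simultaneous component analysis (ASCA) with permutation
    significance testing, PLS1 calibration of oxidation markers (peroxide
    value, K232, K268) with leave-one-material-out cross-validation, and
    reference-chemistry utilities (peroxide value from titration, specific
    extinction coefficients, fatty-acid class sums, three-way ANOVA with
    Tukey post hoc).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
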