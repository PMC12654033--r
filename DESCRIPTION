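Package: spectraquant
Title: Quantification and Chemometrics for Surface-Enhanced Reflectance FTIR Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for label-free immunosensor quantification from near-infrared
    reflectance spectra: delimited-text spectrum input/output and grid alignment,
    zero-phase Butterworth smoothing, improved asymmetric least squares (IASLS)
    baseline correction on a Whittaker penalty, prominence-based peak detection,
    exhaustive calibration-window search scored by linear-regression R-squared,
    classical inverse prediction of analyte concentration, plasmonic enhancement
    factor computation, FFT cross-correlation similarity, PLS latent-variable
    extraction with LDA classification under repeated stratified cross-validation,
    PCA score export, z-scored heatmap matrices, and a seeded band-superposition
    simulator of concentration-responsive reflectance spectra for end-to-end
    testing without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    optparse
Config/testthat/edition: 3
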