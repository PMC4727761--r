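Package: ftirquant
Title: FT-IR Chemometric Quantification of Soy Isoflavone Glycosides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multivariate calibration pipeline for quantifying the isoflavone
    glycosides daidzin, genistin and glycitin (and their total) in complex
    soy-supplement extracts from mid-infrared (FT-IR/ATR) spectra. Implements
    spectral preprocessing (offset and linear baseline correction,
    Savitzky-Golay smoothing and derivatives, standard normal variate,
    wavenumber-region selection), from-scratch PLS1 (NIPALS) regression,
    cross-validated standard-error-of-prediction (SEP) curves with
    latent-variable selection and a quality gate (SEP below 15 percent of the
    property mean), prediction and declared-versus-predicted reporting, plus
    a synthetic spectral generator emulating a standard-addition (spiking)
    calibration design with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
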