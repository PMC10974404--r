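Package: hemoppg
Title: Non-Invasive Hemoglobin Estimation from Multi-Wavelength PPG Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for estimating total hemoglobin concentration
    (g/dL) from eight-wavelength transmissive photoplethysmography (PPG).
    Includes a Beer-Lambert forward model and synthetic cohort generator,
    signal preprocessing (FIR low-pass, coif5 wavelet baseline-drift removal,
    cardiac-period comb filtering), AC/DC ratio-of-ratios feature extraction,
    SVR-based recursive feature elimination, an ensemble extreme learning
    machine regressor, and evaluation tools (RMSE, Pearson correlation,
    Bland-Altman agreement, and a Clarke-style hemoglobin error grid).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
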