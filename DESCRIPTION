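Package: ppgtrend
Title: Hypovolemia Detection from Photoplethysmogram Trend Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discriminates blood loss (hypovolemia) from no blood loss
    (euvolemia) in multi-channel photoplethysmogram (PPG) recordings.
    Implements minimum-Shannon-entropy channel selection, variable-frequency
    complex demodulation (VFCDM) time-frequency spectra, extraction of the
    heart-rate-band amplitude (AM_HR) trend over a 2-minute/1-minute/10-second
    windowing scheme, a four-feature trend vector per recording (r-squared,
    slope, percentage change, signed change), and a balanced, permuted,
    4-fold cross-validated RBF-SVM evaluation protocol with a gamma/C grid
    search. Includes a seeded synthetic PPG generator so the full pipeline
    can be exercised and validated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    signal,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
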