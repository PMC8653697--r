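Package: cardiorqa
Title: Recurrence Quantification and Heart Rate Variability Analysis of
    Rodent Electrocardiograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to characterise cardiac and autonomic dynamics in
    single-lead electrocardiogram (ECG) recordings through nonlinear time
    series analysis.  Provides a synthetic rat ECG generator built from
    Gaussian PQRST wave templates sequenced over spectrally synthesised
    tachograms (with configurable low/high-frequency balance and noise),
    time-domain heart rate variability statistics (SDNN, RMSSD) and
    Poincare map descriptors (SD1, SD2), a complete recurrence
    quantification analysis pipeline (delay selection by average mutual
    information, embedding dimension by false nearest neighbours,
    thresholded recurrence plots and ten recurrence factors), and a
    principal-component projection protocol that scores how close a
    recording's nonlinear signature lies to each simulated cardiac
    condition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse,
    withr
Config/testthat/edition: 3
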