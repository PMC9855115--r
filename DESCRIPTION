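Package: fetalarr
Title: Fetal Arrhythmia Detection from Non-Invasive Abdominal ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects fetal arrhythmia from multichannel abdominal ECG
    recordings. Extracts the fetal ECG by maternal QRS template subtraction,
    detects fetal R-peaks with a Gaussian RR-interval prior, labels 3-second
    signal segments from the cohort RR-interval histogram (normal / moderate /
    arrhythmic, with moderate segments excluded from training), trains a small
    one-dimensional convolutional network on the labeled segments, and
    classifies subjects as healthy or arrhythmic from the fraction of segments
    the network calls arrhythmic. Includes a per-subject mean +/- y*SD
    labeling variant with ternary segment classification, a synthetic cohort
    simulator with ground-truth R-peak sidecars, minimal WFDB and CSV record
    I/O, and leave-one-subject-out evaluation with threshold sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
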