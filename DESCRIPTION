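Package: murineECG
Title: Murine Telemetry ECG Arrhythmia Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detection, delineation and quantification of ventricular
    arrhythmias in murine telemetry electrocardiograms. Provides R-peak
    detection and per-beat fiducial delineation tuned to mouse heart rates
    (300-900 bpm), rule-based classification of ventricular premature beats,
    finite-state detection of bigeminy, trigeminy, salvo and ventricular
    tachycardia patterns, interval metrics including the murine rate-corrected
    QT (QTc = QT / sqrt(RR/100) with RR in ms), stratification of events into
    post-intervention time windows, per-animal count tables and nonparametric
    (Mann-Whitney U) group comparisons. A fully parameterized synthetic
    telemetry-ECG generator with known ground truth - including
    post-infarction morphology stages (ST elevation, hyperacute T waves,
    Q-wave development, deep S waves) and injected arrhythmia events - makes
    the whole pipeline testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
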