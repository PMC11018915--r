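Package: emgait
Title: Stride-Level sEMG and Kinematic Asymmetry Analysis for Equine
    Lameness Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses synchronized surface electromyography
    (sEMG) and upper-body kinematic recordings of trotting horses. Detects
    hindlimb impact events, segments strides, computes stride-level movement
    asymmetry indices (MinDiff, MaxDiff, Hip Hike) from filtered vertical
    displacement, conditions sEMG signals and computes per-stride average
    rectified values (ARV) with outlier removal and baseline-maximum
    normalization, and evaluates how well each parameter discriminates
    non-lame from induced-lameness strides using ROC curves, AUC, and
    Youden-optimal cut-offs. A seeded synthetic-data generator with known
    injected lameness effects makes the whole chain verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite
Config/testthat/edition: 3
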