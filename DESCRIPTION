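Package: mtad
Title: Modified Tip-Apex Distance and Lag-Screw Position Metrics for
    Trochanteric Hip Fractures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes six radiographic lag-screw position parameters for
    dynamic hip screw fixation of trochanteric hip fractures -- tip-apex
    distance (TAD), calcar-referenced TAD, the modified TAD (a direction-aware
    variant whose anteroposterior term is the signed sum of the tip-to-surface
    and surface-to-apex distances), Parker's ratio in both views, Cleveland
    zone and axis-blade angle -- from calibrated two-dimensional landmark
    annotations of paired anteroposterior and lateral radiographs.  Includes a
    synthetic-cohort simulator with a latent mechanical-risk outcome model,
    ROC/AUC analysis with Youden cut-off selection and DeLong confidence
    intervals, the chi-square/exact and Mann-Whitney association tests used in
    cut-out risk studies, and an end-to-end measure/evaluate/flag pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite
Config/testthat/edition: 3
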