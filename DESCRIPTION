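Package: tbsdrift
Title: Baseline EEG/TMS Predictors of Theta-Burst Neuromodulation with
    Drift Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for predicting intermittent theta-burst
    stimulation (iTBS) induced neurophysiological change from baseline
    electrophysiology in two-cohort, two-visit test-retest designs.
    Provides a synthetic TMS-EEG data generator with plantable ground
    truth; multitaper spectral band powers; a single-scale and multiscale
    entropy battery with area-under-curve complexity indices; TMS-evoked
    features (MEP summaries, local mean field power, trial-consistency
    scores); binary outcome labelling via MEP t-tests and LMFP ratios;
    test-retest reliability and dataset-shift diagnostics (ICC(1,1),
    Cohen's kappa, Kolmogorov-Smirnov and Fisher tests, concept-drift
    reporting); and a model-selection harness with stratified repeated
    cross-validation, an admissibility rule, and stratified-bootstrap
    external validation across cross-session, cross-cohort and
    cross-subject designs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    glmnet,
    rpart
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
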