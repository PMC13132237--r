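# tbsdrift

Can baseline electrophysiology predict who responds to intermittent
theta-burst stimulation (iTBS) — and does such a predictor survive a
repeat visit or an independent cohort? `tbsdrift` is an R implementation
of the complete analysis pipeline for that question in a two-cohort,
two-visit test-retest design, aimed at TMS-EEG researchers and
biostatisticians who want the machinery — not a specific dataset —
under test.

The pipeline has five stages, each a package module:

* **Synthesis** — a generator for two-cohort, two-visit TMS-EEG studies
  with plantable ground truth: trait reliability (target ICC),
  trait-to-outcome effect size (log-odds, with its implied Bayes
  ROC-AUC available in closed numerical form), cross-visit outcome
  consistency, and configurable session availability.
* **Features** — multitaper (Slepian) band powers per channel
  (delta/theta/alpha/beta over 1–20 Hz); an entropy battery on the
  first minute of resting EEG: approximate, sample, permutation,
  distribution, incremental entropy and Lempel–Ziv complexity, plus
  multiscale complexity indices (AUC over 20 temporal scales) for
  permutation/sample/distribution entropy under coarse-graining,
  time-shifted and composite procedures; and pre-TBS TMS features (MEP
  mean/SD, local mean field power AUC, a trial-consistency score).
* **Outcomes** — MEP responder labels from two-tailed two-sample
  t-tests (p ≤ 0.05, boundary inclusive), and cortical
  facilitation/suppression labels from LMFP ratios

  LMFP(t) = sqrt( Σᵢ (Vᵢ(t) − V̄(t))² / K ) over the left motor
  channels {C1, C3, C5, FC1, FC3, FC5},

  with ratio(w) = AUC_post(w) / AUC_pre(w) ≥ 1 ⇔ facilitation,
  evaluated over 43 configurable time windows (composite Simpson
  integration).
* **Reliability / drift** — per-feature Kolmogorov–Smirnov covariate
  shift tests, per-method Fisher exact label-shift tests, ICC(1,1) with
  F-based inference, Cohen's kappa with a z-test, consistency
  percentages, and a composite concept-drift verdict.
* **Harness** — feature groups × ROIs × transformations ×
  categorization methods × nine classifiers; 10 × 5 stratified
  cross-validation with t-intervals; exclusion of models under 0.60
  sensitivity or specificity; retraining and stratified-bootstrap
  external validation (2000 resamples) in cross-session, cross-cohort
  and cross-subject designs — with fold-respecting transformation
  fitting, verified by a leakage canary.

The repository is organised as an analysis workflow: all computation
lives in the package (`R/`, compiled entropy kernels in `src/`), and
`analysis/01_simulate.R` … `05_experiments.R` are thin narrative
drivers that run the synthetic study end-to-end and write their tables
under `results/`.

## A worked example

Seventy-three sessions with the study's availability pattern, planted
trait reliability 0.8 and outcome consistency 0.5 — the concept-drift
regime:

```r
library(tbsdrift)

cfg <- synth_config(payload = "traits_only",
                    outcome_consistency = 0.5, seed = 7)
records <- generate_cohorts(cfg)
count_sessions(records)
#>   cohort initial retest total
#> 1      1      17     19    36
#> 2      2      18     19    37
#> 3 pooled      35     38    73

subj <- attr(records, "subjects")
paired <- subj[subj$availability == "both", ]
icc_1_1(cbind(paired$trait_initial, paired$trait_retest))
#> ICC(1,1) = 0.802 [0.639, 0.897], F(32,33) = 9.12, p = 3.763e-09
cohens_kappa(paired$outcome_initial, paired$outcome_retest)
#> kappa = 0.227 (p_o = 0.606, p_e = 0.490), z = 1.37, p = 0.172
```

The baseline feature is highly reliable across visits (ICC 0.80) while
the outcome labels barely agree (kappa 0.23, n.s.) — stable predictors,
unstable predictands. A cross-session experiment (train on initial
visits, validate on retests) shows what that does to a classifier:

```r
ft <- planted_feature_table(records)
gt <- ground_truth_labels(records)
rep <- run_experiment("cross_session", ft,
  list(planted = gt[, c("session_id", "label")]),
  config = list(families = "planted_trait", rois = "whole_scalp",
                transformations = "normalization",
                classifiers = c("lda_ledoit_wolf", "gnb_empirical"),
                seed = 7, n_boot = 2000))
rep
#> Experiment: cross_session ( 35 train / 38 external sessions )
#> Candidates: 2
#> Selected: planted|planted_trait|whole_scalp|normalization|gnb_empirical
#> CV (10 x 5): ROC-AUC 0.906 +/- 0.035, acc 0.779, sens 0.863, spec 0.657
#> External validation (2000 stratified resamples)
#>   accuracy     0.526 [0.395, 0.658]
#>   sensitivity  0.737 [0.526, 0.895]
#>   specificity  0.316 [0.105, 0.526]
#>   f1           0.609 [0.478, 0.723]
#>   precision    0.519 [0.423, 0.625]
#>   roc_auc      0.618 [0.438, 0.789]
#>   pr_auc       0.688 [0.539, 0.845]
```

Internal cross-validation looks excellent (ROC-AUC 0.91); external
validation on the retest visits collapses towards chance (0.62 with a
CI spanning 0.5) — the signature of concept drift: the feature→outcome
mapping, not the features, changed between visits. Raising
`outcome_consistency` to 0.95 closes that gap (see
`tests/testthat/test-acceptance.R` and the methods vignette).

The full-signal pipeline (EEG/TEP tensors, band powers, entropy
battery, LMFP labelling over all 43 windows, drift report, three
experiment designs) is driven by the numbered scripts:

```sh
Rscript analysis/01_simulate.R      # seconds
Rscript analysis/02_features.R      # tens of minutes (entropy battery)
Rscript analysis/03_outcomes.R
Rscript analysis/04_reliability.R
Rscript analysis/05_experiments.R
```

## Documentation

The methods vignette (`vignettes/methods.Rmd`) documents the models and
their assumptions, every convention the literature leaves open (taper
counts, tolerance fractions, tie-breaking, window lists), what the
synthetic generator does and does not emulate, and the package's known
limitations.
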