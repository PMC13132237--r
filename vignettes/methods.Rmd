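---
title: "Predicting theta-burst neuromodulation from baseline EEG: models, diagnostics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting theta-burst neuromodulation from baseline EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tbsdrift)
```

## The problem

Intermittent theta-burst stimulation (iTBS) over primary motor cortex is
expected to change cortical and corticospinal excitability, but individual
responses vary widely. A natural question is whether the *baseline* brain
state — resting EEG spectra and complexity, pre-stimulation TMS-evoked
responses — predicts the direction of that change, and whether such a
predictor survives contact with an independent cohort or a repeat visit.

`tbsdrift` implements the full analysis pipeline for that question in a
two-cohort, two-visit test-retest design: feature extraction, outcome
labelling, test-retest reliability and dataset-shift diagnostics, and a
model-selection/external-validation harness. Because no raw human dataset
is distributed with it, the package ships a synthetic-data generator with
plantable ground truth; every stage is exercised and tested against that
generator, whose parameters are recoverable by the pipeline itself.

## Outcome definitions

**Corticospinal (MEP) outcome.** For each session, peak-to-peak
motor-evoked-potential amplitudes from the pre-TBS block are compared with
a post-TBS block (5 or ~25 minutes after stimulation) by a two-tailed
two-sample t-test at $\alpha = 0.05$. A session is a *responder* when
$p \le 0.05$ in either direction. Welch's unequal-variance test is the
default (the variant is switchable to pooled); the boundary is inclusive.

**Cortical (TEP) outcome.** The local mean field power over the left
motor channels $R = \{C1, C3, C5, FC1, FC3, FC5\}$ is

$$\mathrm{LMFP}(t) = \sqrt{\frac{1}{K}\sum_{i \in R}\bigl(V_i(t) -
\bar V(t)\bigr)^2},$$

with $K = |R|$ and $\bar V$ the instantaneous mean over $R$. The
denominator is $K$, not $K-1$; field-power conventions differ on this and
the choice is deliberate and tested. Windowed areas under the LMFP curve
use composite Simpson integration (a trapezoid correction closes the last
interval when the window holds an even number of samples). The outcome is

$$\mathrm{ratio}(w) = \frac{\mathrm{AUC}\,\mathrm{LMFP}(w)_{\text{post}}}
{\mathrm{AUC}\,\mathrm{LMFP}(w)_{\text{pre}}},$$

averaged across trials within each block before division; a ratio
$\ge 1$ is *facilitation*, below 1 *suppression*. 43 windows are tested
by default: an 11-window 30 ms sweep over 25–345 ms (the last window is
flushed to 345 ms so the span is covered) plus 32 editable a-priori
windows (`inst/extdata/lmfp_windows.json`), including 100–131 ms and
85–115 ms. The exact a-priori composition is a documented stand-in — the
windows matter less than the machinery that sweeps them, and the list is
a configuration input, not a constant.

## Baseline features

**Spectral.** Multitaper power spectral densities (Slepian tapers,
time-bandwidth NW = 4, 7 tapers) per channel and 10-s epoch, band powers
as the area under the density over delta (1–4), theta (4–8), alpha
(8–12) and beta (12–20 Hz), averaged across epochs. Tapers come from the
standard symmetric tridiagonal eigenproblem; for epochs longer than 1024
samples they are computed at 1024 and spline-interpolated, then
re-orthonormalised — Parseval consistency (integral ≈ variance within
5%) is part of the test suite. Knobs the literature leaves open (taper
count, no overlap, demeaning per epoch, trapezoid integration on the
native grid) are fixed defaults, documented here.

**Complexity.** Six single-scale measures per channel — approximate,
sample, permutation ($m=3$), distribution, incremental entropy and
Lempel–Ziv complexity — and twelve multiscale complexity indices:
{permutation $m=2$, permutation $m=3$, sample, distribution} entropy
under coarse-graining, time-shifted and composite procedures, each
summarised as the trapezoid area under the 20-scale entropy curve. All
are computed from the first minute of resting EEG (the first six 10-s
epochs concatenated into one series — concatenation, not per-epoch
averaging, because one long series is what the multiscale reductions
need). Conventions worth stating:

* tolerance for approximate/sample entropy is $0.2\,\mathrm{SD}$ of the
  analysed (scale-reduced) series;
* permutation ties break by temporal index, so results are deterministic
  on quantised data;
* distribution entropy uses 64 bins over the pairwise Chebyshev
  inter-template distances, normalised by $\log_2 64$;
* Lempel–Ziv parses the median-binarised series by the 1976 exhaustive
  production rule, normalised by $n/\log_2 n$;
* incremental entropy codes each increment as a (sign, magnitude) pair
  with magnitude resolution $q=4$ against the increment SD; the original
  formulation is cited but not restated in the source literature we
  follow, so this coding is an explicit in-package definition with
  exposed parameters.

Every measure and every multiscale procedure is checked against an
independent brute-force implementation to $10^{-10}$ in the tests; the
performance-critical pair counting lives in C++.

**Pre-TBS TMS features.** MEP mean and (n−1) SD, the left-motor LMFP AUC
over 15–80 ms, and a regression quality score (RQS) of single-trial TEP
consistency: each trial's ROI-averaged waveform is regressed onto the
leave-one-out average and the median squared correlation is reported.
The RQS formula is a documented approximation of the published composite
score (whose exact form is not restated in the accessible text); it is
bounded in [0, 1], equals 1 for identical non-constant trials, and is
monotone in the template signal-to-noise ratio on synthetic fixtures.
MEP experiments use all four features; LMFP-ratio experiments use only
the two TEP-derived ones (local response only).

## Reliability and shift diagnostics

Covariate shift: per-feature two-sample Kolmogorov–Smirnov tests between
initial and retest sessions. Label shift: per-method two-tailed Fisher
exact tests (chosen over chi-squared for small per-visit counts). All
reported uncorrected, deliberately. Reliability: ICC(1,1) from the
one-way random-effects ANOVA,

$$\mathrm{ICC} = \frac{MS_R - MS_W}{MS_R + (k-1) MS_W},$$

with p from $F = MS_R/MS_W$ and an exact F-based confidence interval
(the interval method is a documented choice; the source text brackets
intervals without naming one). Cohen's kappa uses the standard
$\kappa = (p_o - p_e)/(1 - p_e)$ with the marginal-product chance term;
its z-test uses the large-sample null variance (again a documented
choice). Subjects with a single visit are excluded listwise from paired
analyses.

Concept drift has no formal test; `drift_report()` renders the inference
pattern as an advisory verdict: *drift indicated* when feature
distributions and label proportions are stable (significant fractions at
most twice the test level, feature ICCs high) while outcome reliability
is low (mean kappa and outcome ICC below 0.3). The 0.3 and 2α thresholds
are configurable defaults.

## The harness

Candidates are the Cartesian product of feature families × ROIs
(left motor, central, whole scalp) × transformations, crossed with
categorization methods and nine classifiers: ridge logistic regression
(inner-CV λ), LDA with inner-CV-tuned shrinkage, LDA with Ledoit–Wolf
and with oracle-approximating shrinkage, nearest centroid with Manhattan
and Euclidean metrics, Gaussian naive Bayes with empirical and with
fixed 80–20 priors, and a decision tree (unconstrained depth by
default). Internal assessment is 10 × 5 stratified cross-validation
(t-distribution confidence intervals over the 50 folds); models with
mean sensitivity or specificity below 0.60 are excluded; the highest
mean ROC-AUC among survivors wins, with ties broken by fewer features
then lexicographic id. The winner is retrained on the whole training set
and validated once on the held-out set with 2000 class-stratified
bootstrap resamples for percentile intervals. Chance levels: majority
class for accuracy, 0.5 for ROC-AUC, positive prevalence for PR-AUC.

Two anti-leakage rules are load-bearing and tested. First,
transformation parameters (z-score moments, log-distance medians — the
"normalization" and "log-distance-to-median" feature transformations)
are fit on training folds only; fitting inside folds was an open design
choice and the stricter option was taken. Second, a *leakage canary*:
`cross_validate()` exposes an `eval_mutator` hook that rewrites only the
evaluation fold, and the tests inject a feature equal to the label there
— a fold-respecting pipeline learns a ~zero weight for it and gains
nothing, while any train/eval contamination would ride it towards
perfect scores.

Designs: *cross-session* (train on initial visits, validate on retests),
*cross-cohort* (train on cohort 1 with a visit-type indicator appended,
validate on cohort 2), *cross-subject* (seeded 50/50 subject split, both
visits follow their subject; subject overlap between sides is an error).

## The synthetic generator

`synth_config()` defaults encode the emulated study: cohorts of 21 and
19 subjects with the 15 both / 2 initial-only / 4 retest-only and
18 both / 1 retest-only availability patterns (36 + 37 = 73 sessions);
three minutes of eyes-open resting EEG as 18 × 10-s epochs at 1000 Hz;
pre/T5/T25 single-pulse blocks of 150/150/60 (cohort 1) and 120/120/60
(cohort 2) trials, the latter mirroring the consolidation of the
20- and 30-minute blocks into one "T25" set.

Signals: resting EEG is $1/f$ background plus band-limited Gaussian
oscillations with per-band SDs (delta 4, theta 3, alpha 6, beta 2 µV on
8 µV background — an eyes-open-like, alpha-dominant spectrum). TEP
trials are a deflection template (P30/N45/P60/N100/P180 Gaussian peaks,
so the 100–131 ms window sits on a genuine component) with a *graded*
spatial gain across the left-motor channels plus 2 µV trial noise. The
gradient matters: the LMFP measures dispersion around the ROI mean, so a
spatially uniform evoked response would cancel out of it identically and
no post-TBS scaling could ever reach the labels. MEP amplitudes are
log-normal (median 800 µV, σ_log 0.5), shifted on the log scale in
responders' post blocks.

Ground truth: each subject carries a unit-variance Gaussian trait whose
cross-visit correlation equals `feature_icc_target` (default 0.8,
matching the observed reliability of resting-EEG band powers in this
literature); the trait is exposed directly as the feature
`planted_trait` and also modulates the alpha amplitude weakly so that
extracted spectral features inherit subject reliability. Initial-visit
outcomes are drawn from a logistic model on the trait; the intercept is
solved numerically for the configured prevalence (default 0.6), and
`planted_bayes_auc()` computes the implied ceiling ROC-AUC of the trait
by quadrature, with `effect_for_auc()` as its inverse — the default
effect is the coefficient whose Bayes ROC-AUC is 0.85. Retest outcomes
copy the initial class with probability `outcome_consistency` (default
0.5, the concept-drift regime: raw cross-visit agreement then equals the
consistency parameter exactly, and kappa is centred on zero). The
planted class coherently drives both outcome channels: responders'
post-block MEPs shift, and the post-block TEP template scales by 1.3
(facilitation) or 0.75 (suppression).

What the generator does *not* emulate: TMS artifacts, volume-conduction
topographies beyond the fixed gain profile, preprocessing and artifact
rejection (data are generated "clean" — the emulated study's
preprocessing chain is unavailable and is explicitly out of scope), and
any nonstationarity within a session. Passing tests therefore certify
the statistical machinery and its calibration, not robustness to real
measurement artifacts.

## Numerical and testing choices

* Degenerate inputs are pinned by tests: constant series (sample entropy
  0 with a note), zero-variance trials (RQS term 0 with a note),
  zero-variance t-tests (p = 1 on equal means), all-identical ICC tables
  (error, 0/0), double-constant kappa (error, $p_e = 1$), zero pre-TBS
  LMFP AUC (error, undefined ratio).
* Ties: permutation patterns break by temporal index; model selection
  breaks by feature count then id; ROC ties count one half
  (Mann–Whitney identity, cross-checked against pROC).
* Problem sizes: statistical calibration runs use the `traits_only`
  payload (no signal tensors) at 100–500 subjects — large enough that
  estimator noise is small against the tested tolerances. The
  concept-drift fixture uses 250 subjects per cohort with
  `feature_icc_target = 1`: the control arm is meant to isolate outcome
  consistency, and with imperfect trait reliability the external score
  is attenuated by the trait autocorrelation (asymptotically the
  internal/external gap stays ≈ 0.10 at ICC 0.8 even with 95% outcome
  consistency), which would confound the comparison. The analysis
  scripts run the full-signal study at 125 Hz with an 8-channel montage
  and 30/30/15-trial blocks — scaled-down but structurally faithful
  defaults, stated here as the package's own demo scale.
* The exact type-I behaviour of Fisher's exact test is conservative at
  small per-visit counts; calibration checks use 100 labels per visit
  (and 60 per sample for KS), sizes at which the empirical level sits
  inside 0.05 ± 0.02.

## Known limitations

The RQS and incremental-entropy formulas are documented stand-ins for
published definitions not restated here. The 43-window list's a-priori
half is a configurable surrogate. The generator's EEG is stationary
Gaussian; complexity differences between subjects enter only through the
planted trait's alpha coupling, so absolute entropy values should not be
compared against human data. Cohort-specific published performance
numbers are not reproduction targets: the underlying recordings are not
public, and this package's claims are about the machinery — calibration,
oracle equivalence, parameter recovery and the qualitative
internal-versus-external concept-drift signature, each of which the test
suite and `scripts/acceptance.R` recompute from scratch.
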