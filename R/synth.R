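#' Default synthetic montage
#'
#' Twenty 10-10 channel labels covering the left motor and central ROIs
#' plus surrounding scalp.
#'
#' @return Character vector of channel names.
#' @export
default_channels <- function() {
  c("Fp1", "Fp2", "F3", "Fz", "F4", "FC5", "FC3", "FC1", "FCz", "FC2",
    "C5", "C3", "C1", "Cz", "C2", "CPz", "P3", "Pz", "P4", "Oz")
}

#' Bayes ROC-AUC implied by the planted logistic effect
#'
#' The generator draws a unit-variance Gaussian trait `x` per session and
#' an outcome `y ~ Bernoulli(plogis(a + b x))`, with the intercept `a`
#' solved so the marginal positive rate matches `positive_rate`. This
#' function returns the ROC-AUC of the trait itself as a score,
#' `P(x+ > x-)`, by deterministic quadrature - the ceiling any classifier
#' using the planted feature can reach.
#'
#' @param effect Log-odds coefficient `b`.
#' @param positive_rate Marginal positive prevalence.
#' @return List `auc`, `intercept`.
#' @export
planted_bayes_auc <- function(effect, positive_rate = 0.6) {
  x <- seq(-8, 8, by = 0.002)
  phi <- stats::dnorm(x)
  dx <- 0.002
  prev <- function(a) sum(stats::plogis(a + effect * x) * phi) * dx
  a <- stats::uniroot(function(a) prev(a) - positive_rate, c(-30, 30))$root
  p1 <- stats::plogis(a + effect * x) * phi        # joint density of (x, y=1)
  p0 <- (1 - stats::plogis(a + effect * x)) * phi  # joint density of (x, y=0)
  p <- sum(p1) * dx
  # P(X1 > X0) + 0.5 P(X1 = X0): cumulative of p0 below each x
  F0 <- (cumsum(p0) - p0 / 2) * dx
  auc <- sum(p1 * F0) * dx / (p * (1 - p))
  list(auc = auc, intercept = a)
}

#' Planted effect size for a target Bayes ROC-AUC
#'
#' Inverts [planted_bayes_auc()] over the log-odds coefficient.
#'
#' @param auc Target Bayes ROC-AUC in (0.5, 1).
#' @param positive_rate Marginal positive prevalence.
#' @return Log-odds coefficient.
#' @export
effect_for_auc <- function(auc, positive_rate = 0.6) {
  stats::uniroot(function(b) planted_bayes_auc(b, positive_rate)$auc - auc,
                 c(1e-6, 20))$root
}

#' Synthetic study configuration
#'
#' Defaults emulate the two-cohort test-retest design: cohort 1 with 21
#' subjects (15 with both visits, 2 initial-only, 4 retest-only), cohort 2
#' with 19 (18 both, 1 retest-only); three minutes of eyes-open rsEEG as
#' 18 x 10-s epochs at 1000 Hz; pre/T5/T25 single-pulse blocks with
#' per-cohort trial counts (150/150/60 and 120/120/60); MEP amplitudes
#' log-normal; TEPs a deflection template (P30/N45/P60/N100/P180) plus
#' trial noise, the post-TBS template scaled up for planted facilitation
#' and down for suppression.
#'
#' Ground truth is plantable: `feature_icc_target` sets the cross-visit
#' correlation of the subject trait exposed as feature `planted_trait`;
#' `effect` is the log-odds coefficient linking that trait to the session
#' outcome class (see [planted_bayes_auc()]); `outcome_consistency` is
#' the probability the outcome class repeats at retest.
#'
#' @param n_subjects_per_cohort Integer vector, subjects per cohort.
#' @param initial_only,retest_only Per-cohort counts of subjects with only
#'   one visit; the remainder have both.
#' @param fs Sampling rate (Hz).
#' @param n_epochs Number of 10-s rsEEG epochs.
#' @param epoch_s Epoch length (s).
#' @param channels Montage channel names (unique).
#' @param band_amplitudes Per-band oscillation SD (uV).
#' @param noise_sd SD of the 1/f background (uV).
#' @param feature_icc_target Intended ICC of the planted trait, in [0,1].
#' @param effect Planted log-odds coefficient (default: the value whose
#'   Bayes ROC-AUC is 0.85 at the default prevalence).
#' @param positive_rate Marginal positive-class prevalence.
#' @param outcome_consistency Probability the outcome repeats at retest.
#' @param mep_params List `meanlog`, `sdlog`, `modulation` (log-scale MEP
#'   shift in responders) and `n_trials` (per-cohort list of pre/T5/T25
#'   counts).
#' @param tep_mod Multiplicative post-TBS template gain
#'   `c(positive, negative)`.
#' @param tep_noise_sd Trial noise SD (uV).
#' @param tep_span_ms TEP support after the pulse (ms).
#' @param payload `"full"` generates rsEEG/TEP tensors; `"traits_only"`
#'   generates only traits, outcomes, and MEP vectors (for large-n
#'   statistical calibration).
#' @param seed Integer seed; same seed, same dataset.
#' @return A `synth_config`.
#' @export
synth_config <- function(n_subjects_per_cohort = c(21L, 19L),
                         initial_only = c(2L, 0L),
                         retest_only = c(4L, 1L),
                         fs = 1000, n_epochs = 18L, epoch_s = 10,
                         channels = default_channels(),
                         band_amplitudes = c(delta = 4, theta = 3,
                                             alpha = 6, beta = 2),
                         noise_sd = 8,
                         feature_icc_target = 0.8,
                         effect = NULL,
                         positive_rate = 0.6,
                         outcome_consistency = 0.5,
                         mep_params = list(
                           meanlog = log(800), sdlog = 0.5,
                           modulation = 0.4,
                           n_trials = list(c(pre = 150, T5 = 150,
                                             T25 = 60),
                                           c(pre = 120, T5 = 120,
                                             T25 = 60))),
                         tep_mod = c(positive = 1.3, negative = 0.75),
                         tep_noise_sd = 2,
                         tep_span_ms = 350,
                         payload = c("full", "traits_only"),
                         seed = 1L) {
  payload <- match.arg(payload)
  n_coh <- length(n_subjects_per_cohort)
  if (any(n_subjects_per_cohort < 0)) stop("subject counts must be >= 0")
  if (length(initial_only) != n_coh || length(retest_only) != n_coh)
    stop("per-cohort missingness must match the number of cohorts")
  if (any(initial_only < 0) || any(retest_only < 0))
    stop("missingness counts must be >= 0")
  if (any(initial_only + retest_only > n_subjects_per_cohort))
    stop("missingness counts exceed the cohort subject count")
  if (fs <= 0) stop("fs must be > 0")
  if (anyDuplicated(channels)) stop("channel names must be unique")
  if (feature_icc_target < 0 || feature_icc_target > 1 ||
      outcome_consistency < 0 || outcome_consistency > 1 ||
      positive_rate <= 0 || positive_rate >= 1)
    stop("probabilities must lie in [0, 1]")
  if (is.null(effect)) effect <- effect_for_auc(0.85, positive_rate)
  structure(list(
    n_subjects_per_cohort = as.integer(n_subjects_per_cohort),
    initial_only = as.integer(initial_only),
    retest_only = as.integer(retest_only),
    fs = fs, n_epochs = as.integer(n_epochs), epoch_s = epoch_s,
    channels = channels, band_amplitudes = band_amplitudes,
    noise_sd = noise_sd, feature_icc_target = feature_icc_target,
    effect = effect, positive_rate = positive_rate,
    outcome_consistency = outcome_consistency, mep_params = mep_params,
    tep_mod = tep_mod, tep_noise_sd = tep_noise_sd,
    tep_span_ms = tep_span_ms, payload = payload, seed = as.integer(seed)),
    class = "synth_config")
}

#' Session record
#'
#' One subject-visit bundle: resting-state EEG epochs, MEP amplitude
#' blocks, TEP trial tensors and metadata.
#'
#' @param session_id,subject_id,cohort_id,visit Identity fields
#'   (`visit` is `"initial"` or `"retest"`).
#' @param fs Sampling rate (Hz).
#' @param rs_eeg Epochs x channels x samples array (uV) or `NULL`.
#' @param mep_blocks Named list (`pre`, `T5`, `T25`) of amplitude vectors.
#' @param tep_blocks Named list of trials x channels x time arrays.
#' @param tep_time Time axis (ms, 0 = pulse), strictly increasing.
#' @param planted List of generator ground truth (trait, outcome class).
#' @return A `session_record`.
#' @export
session_record <- function(session_id, subject_id, cohort_id, visit, fs,
                           rs_eeg = NULL, mep_blocks = list(),
                           tep_blocks = list(), tep_time = NULL,
                           planted = NULL) {
  if (!visit %in% c("initial", "retest"))
    stop("visit must be 'initial' or 'retest'")
  if (!is.null(tep_time) && any(diff(tep_time) <= 0))
    stop("TEP time axis must be strictly increasing")
  for (b in mep_blocks)
    if (any(!is.finite(b))) stop("MEP amplitudes must be finite")
  structure(list(session_id = session_id, subject_id = subject_id,
                 cohort_id = cohort_id, visit = visit, fs = fs,
                 rs_eeg = rs_eeg, mep_blocks = mep_blocks,
                 tep_blocks = tep_blocks, tep_time = tep_time,
                 planted = planted),
            class = "session_record")
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("<session_record> %s (cohort %d, %s)\n", x$session_id,
              x$cohort_id, x$visit))
  invisible(x)
}

# 1/f (beta = 1) coloured noise via spectral shaping, unit variance.
pink_noise <- function(n) {
  white <- stats::rnorm(n)
  sp <- stats::fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)  # mirrored frequency index
  sp <- sp / sqrt(f)
  x <- Re(stats::fft(sp, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Band-limited Gaussian oscillation: white noise FFT-masked to [lo, hi] Hz,
# unit variance.
band_oscillation <- function(n, fs, lo, hi) {
  white <- stats::rnorm(n)
  sp <- stats::fft(white)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  mask <- f >= lo & f <= hi
  if (!any(mask)) return(numeric(n))
  sp[!mask] <- 0
  x <- Re(stats::fft(sp, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) numeric(n) else x / s
}

# Deflection template: Gaussian-windowed peaks emulating P30/N45/P60/
# N100/P180, so the 100-131 ms window sits on a real component.
tep_template <- function(t_ms) {
  peaks <- list(c(30, 8, 3), c(45, 12, -6), c(60, 15, 4),
                c(100, 25, -8), c(180, 40, 5))
  v <- numeric(length(t_ms))
  for (pk in peaks)
    v <- v + pk[3] * exp(-(t_ms - pk[1])^2 / (2 * pk[2]^2))
  v
}

# Per-channel spatial gain of the evoked response: strong but graded over
# the left motor ROI, attenuated elsewhere. The within-ROI gradient is
# essential: the local mean field power measures dispersion around the
# ROI mean, so a spatially uniform response would cancel out of it
# entirely and the planted post-TBS scaling would be invisible.
tep_gain <- function(channels) {
  roi <- intersect(left_motor_channels(), channels)
  other <- setdiff(channels, roi)
  g <- numeric(length(channels))
  names(g) <- channels
  if (length(roi))
    g[roi] <- seq(0.5, 1.5, length.out = max(length(roi), 2))[
      seq_along(roi)]
  if (length(other))
    g[other] <- seq(0.2, 0.45, length.out = max(length(other), 2))[
      seq_along(other)]
  g
}

#' Generate the synthetic two-cohort, two-visit dataset
#'
#' Deterministic given the config seed. Subject traits are shared across
#' visits with cross-visit correlation equal to `feature_icc_target`;
#' initial-visit outcomes are drawn from a logistic model on the trait;
#' retest outcomes repeat the initial class with probability
#' `outcome_consistency` and flip otherwise. rsEEG is 1/f background plus
#' band-limited oscillations (the alpha amplitude is weakly modulated by
#' the trait, so extracted spectral features inherit subject
#' reliability). MEP amplitudes are log-normal with a log-scale shift in
#' responders' post blocks; TEP trials are the template plus noise, the
#' post-block template scaled by the planted class.
#'
#' @param config A [synth_config()].
#' @return List of [session_record()]s (attribute `subjects`: the ground
#'   truth table).
#' @export
generate_cohorts <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  icc <- config$feature_icc_target
  a0 <- planted_bayes_auc(config$effect, config$positive_rate)$intercept
  n_samp <- round(config$fs * config$epoch_s)
  t_ms <- seq(0, config$tep_span_ms, by = 1000 / config$fs)
  template <- tep_template(t_ms)
  gain <- tep_gain(config$channels)
  bands <- default_bands()

  records <- list()
  subjects <- list()
  for (coh in seq_along(config$n_subjects_per_cohort)) {
    n <- config$n_subjects_per_cohort[coh]
    if (n == 0) next
    avail <- c(rep("initial_only", config$initial_only[coh]),
               rep("retest_only", config$retest_only[coh]),
               rep("both", n - config$initial_only[coh] -
                     config$retest_only[coh]))
    mp <- config$mep_params
    n_trials <- mp$n_trials[[min(coh, length(mp$n_trials))]]
    for (s in seq_len(n)) {
      subject_id <- sprintf("c%ds%02d", coh, s)
      z <- stats::rnorm(1)
      trait <- sqrt(icc) * z + sqrt(1 - icc) * stats::rnorm(2)
      names(trait) <- c("initial", "retest")
      y_init <- stats::rbinom(1, 1, stats::plogis(a0 + config$effect *
                                                    trait["initial"]))
      y_ret <- if (stats::runif(1) < config$outcome_consistency)
        y_init else 1L - y_init
      y <- c(initial = y_init, retest = unname(y_ret))
      mep_dir <- sample(c(-1, 1), 1)  # responder modulation direction
      subjects[[length(subjects) + 1L]] <- data.frame(
        subject_id = subject_id, cohort = coh,
        availability = avail[s],
        trait_initial = unname(trait["initial"]),
        trait_retest = unname(trait["retest"]),
        outcome_initial = y_init, outcome_retest = unname(y_ret))
      visits <- switch(avail[s], both = c("initial", "retest"),
                       initial_only = "initial", retest_only = "retest")
      for (v in visits)
        records[[length(records) + 1L]] <-
          generate_session(config, subject_id, coh, v, trait[v], y[[v]],
                           mep_dir, n_trials, n_samp, t_ms, template,
                           gain, bands)
    }
  }
  attr(records, "subjects") <- if (length(subjects))
    do.call(rbind, subjects) else NULL
  records
}

generate_session <- function(config, subject_id, coh, visit, trait, y,
                             mep_dir, n_trials, n_samp, t_ms, template,
                             gain, bands) {
  n_ch <- length(config$channels)
  rs_eeg <- NULL
  tep_blocks <- list()
  mep_blocks <- list()
  mp <- config$mep_params
  full <- config$payload == "full"
  if (full) {
    rs_eeg <- array(0, dim = c(config$n_epochs, n_ch, n_samp),
                    dimnames = list(NULL, config$channels, NULL))
    alpha_scale <- exp(0.15 * trait)
    for (e in seq_len(config$n_epochs))
      for (ch in seq_len(n_ch)) {
        x <- config$noise_sd * pink_noise(n_samp)
        for (b in bands) {
          amp <- config$band_amplitudes[[b$name]]
          if (b$name == "alpha") amp <- amp * alpha_scale
          x <- x + amp * band_oscillation(n_samp, config$fs, b$lo, b$hi)
        }
        rs_eeg[e, ch, ] <- x
      }
  }
  for (block in c("pre", "T5", "T25")) {
    shift <- if (block != "pre" && y == 1) mep_dir * mp$modulation else 0
    mep_blocks[[block]] <- stats::rlnorm(n_trials[[block]],
                                         mp$meanlog + shift, mp$sdlog)
    if (full) {
      g <- if (block == "pre") 1
           else if (y == 1) config$tep_mod[["positive"]]
           else config$tep_mod[["negative"]]
      arr <- array(0, dim = c(n_trials[[block]], n_ch, length(t_ms)),
                   dimnames = list(NULL, config$channels, t_ms))
      base <- outer(gain, template * g)
      for (tr in seq_len(n_trials[[block]]))
        arr[tr, , ] <- base + config$tep_noise_sd *
          matrix(stats::rnorm(n_ch * length(t_ms)), n_ch)
      tep_blocks[[block]] <- arr
    }
  }
  session_record(
    session_id = paste0(subject_id, "_", visit), subject_id = subject_id,
    cohort_id = coh, visit = visit, fs = config$fs, rs_eeg = rs_eeg,
    mep_blocks = mep_blocks, tep_blocks = tep_blocks, tep_time = t_ms,
    planted = list(trait = unname(trait), outcome_class = y))
}

#' Session accounting
#'
#' Exact per-cohort and pooled counts of initial, retest and total
#' sessions.
#'
#' @param records List of [session_record()]s.
#' @return A `session_accounting` data frame with one row per cohort and
#'   a pooled row.
#' @export
count_sessions <- function(records) {
  if (length(records) == 0)
    return(structure(data.frame(cohort = "pooled", initial = 0L,
                                retest = 0L, total = 0L),
                     class = c("session_accounting", "data.frame")))
  coh <- vapply(records, `[[`, numeric(1), "cohort_id")
  vis <- vapply(records, `[[`, character(1), "visit")
  rows <- lapply(sort(unique(coh)), function(cc)
    data.frame(cohort = as.character(cc),
               initial = sum(coh == cc & vis == "initial"),
               retest = sum(coh == cc & vis == "retest"),
               total = sum(coh == cc)))
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(cohort = "pooled",
                               initial = sum(out$initial),
                               retest = sum(out$retest),
                               total = sum(out$total)))
  structure(out, class = c("session_accounting", "data.frame"))
}

#' Ground-truth feature table from generated records
#'
#' The planted trait and session metadata as a wide feature table suitable
#' for [run_experiment()]; used for statistical calibration where the
#' signal-level feature extraction is not under study.
#'
#' @param records List of [session_record()]s.
#' @return Data frame `session_id, subject_id, cohort, visit,
#'   planted_trait` (attribute `channels` empty).
#' @export
planted_feature_table <- function(records) {
  out <- do.call(rbind, lapply(records, function(s)
    data.frame(session_id = s$session_id, subject_id = s$subject_id,
               cohort = s$cohort_id, visit = s$visit,
               planted_trait = s$planted$trait)))
  attr(out, "channels") <- character(0)
  out
}

#' Ground-truth outcome labels from generated records
#'
#' @param records List of [session_record()]s.
#' @return Data frame `session_id, subject_id, visit, label` with the
#'   planted outcome class (`positive` = facilitation/responder).
#' @export
ground_truth_labels <- function(records) {
  do.call(rbind, lapply(records, function(s)
    data.frame(session_id = s$session_id, subject_id = s$subject_id,
               visit = s$visit,
               label = if (s$planted$outcome_class == 1) "positive"
                       else "negative")))
}
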