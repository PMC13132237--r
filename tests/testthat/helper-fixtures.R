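# Shared small fixtures, built in code at test time.

# A minimal full-payload config: 6-channel montage, short blocks, low
# sampling rate. Keeps full-pipeline tests in the seconds range.
tiny_config <- function(seed = 42, ...) {
  args <- utils::modifyList(list(
    n_subjects_per_cohort = c(3L, 2L), initial_only = c(1L, 0L),
    retest_only = c(1L, 0L), fs = 200, n_epochs = 6L,
    channels = c("C1", "C3", "C5", "FC1", "FC3", "FC5"),
    mep_params = list(meanlog = log(800), sdlog = 0.5, modulation = 0.4,
                      n_trials = list(c(pre = 20, T5 = 20, T25 = 10),
                                      c(pre = 15, T5 = 15, T25 = 10))),
    seed = seed), list(...))
  do.call(synth_config, args)
}

# Large-n trait-only config for statistical calibration.
traits_config <- function(n, seed = 1, ...) {
  args <- utils::modifyList(list(
    n_subjects_per_cohort = c(n, 0L), initial_only = c(0L, 0L),
    retest_only = c(0L, 0L), payload = "traits_only", seed = seed),
    list(...))
  do.call(synth_config, args)
}

# Hand-built session with deterministic payloads.
manual_session <- function(rs = NULL, mep = list(), tep = list(),
                           tep_time = NULL, fs = 100, visit = "initial",
                           id = "s1_initial") {
  session_record(session_id = id, subject_id = "s1", cohort_id = 1L,
                 visit = visit, fs = fs, rs_eeg = rs, mep_blocks = mep,
                 tep_blocks = tep, tep_time = tep_time)
}

# trials x channels x time TEP array from a channels x time matrix
# repeated with additive noise.
tep_array <- function(base, n_trials, noise_sd = 0, seed = 1) {
  set.seed(seed)
  arr <- array(0, dim = c(n_trials, nrow(base), ncol(base)),
               dimnames = list(NULL, rownames(base), colnames(base)))
  for (i in seq_len(n_trials))
    arr[i, , ] <- base + matrix(rnorm(length(base), sd = noise_sd),
                                nrow(base))
  arr
}
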