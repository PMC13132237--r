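# Shared configuration for the analysis scripts.
#
# The synthetic study mirrors the two-cohort test-retest design (21 + 19
# subjects with the 15/2/4 and 18/0/1 availability pattern) at a reduced
# signal scale chosen for desk runtime: 125 Hz sampling, an 8-channel
# montage around left motor cortex, and 30/30/15-trial TMS blocks. The
# planted ground truth uses the package defaults: trait reliability 0.8,
# a trait-outcome effect whose Bayes ROC-AUC is 0.85, and cross-visit
# outcome consistency 0.5 (the concept-drift regime).

library(tbsdrift)

# run the scripts from the repository root: Rscript analysis/01_simulate.R
ANALYSIS_SEED <- 20260927L
RESULTS_DIR <- "results"

analysis_channels <- c("C1", "C3", "C5", "FC1", "FC3", "FC5", "Cz", "CPz")

analysis_config <- function() {
  # positive_rate 0.5: balanced facilitation/suppression keeps class
  # proportions stable across visits (the consistency resampling pulls
  # retest marginals to 0.5, so an unbalanced prevalence would add label
  # shift on top of the concept drift this demo is about)
  synth_config(
    fs = 125, n_epochs = 6L, channels = analysis_channels,
    positive_rate = 0.5,
    mep_params = list(meanlog = log(800), sdlog = 0.5, modulation = 0.4,
                      n_trials = list(c(pre = 30, T5 = 30, T25 = 15),
                                      c(pre = 24, T5 = 24, T25 = 15))),
    seed = ANALYSIS_SEED)
}

results_path <- function(name) {
  dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)
  file.path(RESULTS_DIR, name)
}
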