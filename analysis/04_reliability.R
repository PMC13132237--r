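# Stage 4: dataset-shift and reliability diagnostics. Univariate KS
# tests for covariate shift (initial vs retest, per feature), Fisher
# exact tests for label shift (per categorization method), ICC(1,1) for
# feature and outcome reliability, Cohen's kappa and consistency
# percentages for the labels, and the composite concept-drift verdict.

source("analysis/00_config.R")

cfg <- analysis_config()
records <- generate_cohorts(cfg)
features <- read.csv(results_path("02_features.csv"))
labels <- read.csv(results_path("03_labels.csv"))

meta <- do.call(rbind, lapply(records, function(s)
  data.frame(session_id = s$session_id, subject_id = s$subject_id,
             visit = s$visit, cohort = s$cohort_id)))
label_sets <- lapply(split(labels, labels$method), function(d)
  merge(meta, d[, c("session_id", "diagnostic", "label")],
        by = "session_id"))

rep <- drift_report(features, label_sets)
print(rep)

# spectral vs complexity KS-significant fractions, as separate families
is_spec <- grepl("^bp_", rep$ks$feature)
is_cplx <- grepl("^en_|_ci_", rep$ks$feature)
summary <- list(
  frac_ks_significant_spectral = mean(rep$ks$p[is_spec] <= 0.05),
  frac_ks_significant_complexity = mean(rep$ks$p[is_cplx] <= 0.05),
  frac_fisher_significant = rep$frac_fisher_significant,
  mean_feature_icc = rep$mean_feature_icc,
  mean_kappa_lmfp = mean(rep$labels$kappa[grepl("^lmfp",
                                                rep$labels$method)],
                         na.rm = TRUE),
  kappa_mep_t5 = rep$labels$kappa[rep$labels$method == "mep_t5"],
  kappa_mep_t25 = rep$labels$kappa[rep$labels$method == "mep_t25"],
  mean_consistency_pct_lmfp =
    mean(rep$labels$consistency_pct[grepl("^lmfp", rep$labels$method)]),
  consistency_pct_mep_t5 =
    rep$labels$consistency_pct[rep$labels$method == "mep_t5"],
  verdict = rep$verdict)
str(summary)

jsonlite::write_json(summary, results_path("04_reliability.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
write.csv(rep$ks, results_path("04_ks_tests.csv"), row.names = FALSE)
write.csv(rep$labels, results_path("04_outcome_reliability.csv"),
          row.names = FALSE)
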