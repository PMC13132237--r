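# Stage 5: model generation, selection and external validation in the
# three experiment designs. The candidate universe is a demo-scale sweep
# (two feature families x three ROIs x two transformations x the nine
# classifiers) rather than the full combinatorial space; the harness
# supports larger universes via the config.

source("analysis/00_config.R")

cfg <- analysis_config()
records <- generate_cohorts(cfg)
features <- read.csv(results_path("02_features.csv"))
attr(features, "channels") <- analysis_channels
labels <- read.csv(results_path("03_labels.csv"))

lab_set <- function(method)
  labels[labels$method == method, c("session_id", "label")]

families <- c("cgmse_disten_m2_ci", "bp_alpha")
base_config <- list(
  families = families,
  rois = c("left_motor", "central", "whole_scalp"),
  transformations = c("normalization", "log_distance_to_median"),
  classifiers = classifier_ids(),
  reps = 10L, folds = 5L, n_boot = 2000L, seed = ANALYSIS_SEED,
  include_pretbs = TRUE)

# LMFP ratio experiment: only TEP-derived pre-TBS features
feat_lmfp <- features[, !grepl("^pre_mep_", colnames(features))]
attr(feat_lmfp, "channels") <- analysis_channels

save_report <- function(rep, name) {
  write.csv(rep$candidate_table,
            results_path(paste0(name, "_candidates.csv")),
            row.names = FALSE)
  sel <- if (inherits(rep$selected, "no_admissible_model"))
    list(no_admissible_model = TRUE)
  else list(id = rep$selected$id,
            internal = as.list(rep$selected$cv$mean),
            internal_ci_half = as.list(rep$selected$cv$ci_half),
            external = as.list(rep$external$point),
            external_ci = list(lo = as.list(rep$external$ci[1, ]),
                               hi = as.list(rep$external$ci[2, ])),
            chance = as.list(rep$external$chance))
  jsonlite::write_json(list(design = rep$design, n_train = rep$n_train,
                            n_external = rep$n_external, selected = sel),
                       results_path(paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

run_one <- function(design, feats, method, name) {
  t0 <- Sys.time()
  rep <- run_experiment(design, feats, setNames(list(lab_set(method)),
                                                method), base_config)
  cat("\n==", name, "(", format(Sys.time() - t0), ")\n")
  print(rep)
  save_report(rep, name)
  invisible(rep)
}

run_one("cross_cohort", feat_lmfp, "lmfp_100_131",
        "05_cross_cohort_lmfp")
run_one("cross_session", features, "mep_t5", "05_cross_session_mep")
run_one("cross_subject", feat_lmfp, "lmfp_85_115",
        "05_cross_subject_lmfp")
cat("\nDone.\n")
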