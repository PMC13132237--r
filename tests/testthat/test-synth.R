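test_that("generator config validation and the empty case", {
  expect_error(synth_config(n_subjects_per_cohort = c(3, 3),
                            initial_only = c(2, 0),
                            retest_only = c(2, 0)), "exceed")
  expect_error(synth_config(channels = c("C1", "C1")), "unique")
  expect_error(synth_config(fs = 0), "fs")
  empty <- synth_config(n_subjects_per_cohort = c(0L, 0L),
                        initial_only = c(0L, 0L),
                        retest_only = c(0L, 0L), payload = "traits_only")
  expect_length(generate_cohorts(empty), 0)
})

test_that("the same seed reproduces the dataset exactly", {
  cfg <- tiny_config(seed = 123)
  r1 <- generate_cohorts(cfg)
  r2 <- generate_cohorts(cfg)
  expect_identical(r1, r2)
  r3 <- generate_cohorts(tiny_config(seed = 124))
  expect_false(identical(r1[[1]]$rs_eeg, r3[[1]]$rs_eeg))
})

test_that("session accounting matches the availability pattern", {
  cfg <- tiny_config(seed = 5)
  rec <- generate_cohorts(cfg)
  acc <- count_sessions(rec)
  # cohort 1: 1 both + 1 initial-only + 1 retest-only = 4 sessions
  expect_equal(acc$total[acc$cohort == "1"], 4)
  expect_equal(acc$total[acc$cohort == "pooled"], length(rec))
  expect_equal(acc$initial + acc$retest, acc$total)
})

test_that("planted trait reliability is recovered by ICC", {
  cfg <- traits_config(100, seed = 31, feature_icc_target = 0.8)
  rec <- generate_cohorts(cfg)
  subj <- attr(rec, "subjects")
  icc <- icc_1_1(cbind(subj$trait_initial, subj$trait_retest))$icc
  expect_lt(abs(icc - 0.8), 0.1)
})

test_that("outcome consistency controls cross-visit label agreement", {
  cfg <- traits_config(200, seed = 33, outcome_consistency = 0.5)
  subj <- attr(generate_cohorts(cfg), "subjects")
  kap <- cohens_kappa(subj$outcome_initial, subj$outcome_retest)$kappa
  expect_lt(abs(kap), 0.15)
  pct <- consistency_percentage(subj$outcome_initial,
                                subj$outcome_retest)
  expect_lt(abs(pct - 50), 7)
  # full consistency repeats every label
  cfg1 <- traits_config(50, seed = 34, outcome_consistency = 1)
  subj1 <- attr(generate_cohorts(cfg1), "subjects")
  expect_equal(subj1$outcome_initial, subj1$outcome_retest)
})

test_that("planted prevalence and effect behave as configured", {
  cfg <- traits_config(400, seed = 35, positive_rate = 0.6)
  rec <- generate_cohorts(cfg)
  gt <- ground_truth_labels(rec)
  # the logistic intercept targets the prevalence of the initial draws
  # (retest labels are consistency-resampled copies)
  ini <- gt$label[gt$visit == "initial"]
  expect_lt(abs(mean(ini == "positive") - 0.6), 0.06)
  # zero effect: the trait carries no outcome information, and the
  # cross-validated harness sits at chance at n = 200 (averaged over
  # three generated datasets; a single draw's AUC has SD ~0.04, so the
  # mean is the better-conditioned estimate of the chance level)
  aucs <- sapply(36:38, function(s) {
    cfg0 <- traits_config(200, seed = s, effect = 0,
                          outcome_consistency = 1)
    rec0 <- Filter(function(r) r$visit == "initial",
                   generate_cohorts(cfg0))
    ft <- planted_feature_table(rec0)
    gt0 <- ground_truth_labels(rec0)
    cv <- cross_validate("lda_ledoit_wolf",
                         ft[, "planted_trait", drop = FALSE],
                         setNames(gt0$label,
                                  gt0$session_id)[ft$session_id],
                         seed = s)
    cv$mean["roc_auc"]
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.07)
})

test_that("Bayes ROC-AUC quadrature agrees with Monte Carlo", {
  b <- effect_for_auc(0.85, 0.6)
  expect_equal(planted_bayes_auc(b, 0.6)$auc, 0.85, tolerance = 1e-4)
  set.seed(37)
  n <- 2e5
  x <- rnorm(n)
  a <- planted_bayes_auc(b, 0.6)$intercept
  y <- ifelse(rbinom(n, 1, plogis(a + b * x)) == 1, "positive",
              "negative")
  expect_lt(abs(roc_auc(y, x) - 0.85), 0.01)
})

test_that("full-payload sessions carry coherent physiology", {
  cfg <- tiny_config(seed = 61)
  rec <- generate_cohorts(cfg)
  s <- rec[[1]]
  expect_equal(dim(s$rs_eeg), c(6, 6, 2000))
  expect_true(all(is.finite(s$rs_eeg)))
  expect_true(all(diff(s$tep_time) > 0))
  expect_equal(dimnames(s$tep_blocks$pre)[[2]], cfg$channels)
  expect_length(s$mep_blocks$pre, 20)
  # planted positive class raises the post/pre LMFP ratio above 1
  pos <- Filter(function(r) r$planted$outcome_class == 1, rec)
  neg <- Filter(function(r) r$planted$outcome_class == 0, rec)
  if (length(pos) && length(neg)) {
    ratio_of <- function(r)
      lmfp_ratio(r$tep_blocks$pre, r$tep_blocks$T5,
                 w = tep_window(100, 131), t = r$tep_time)$ratio
    rp <- sapply(pos, ratio_of); rn <- sapply(neg, ratio_of)
    expect_gt(mean(rp), 1)
    expect_lt(mean(rn), 1)
    expect_gt(mean(rp), mean(rn) + 0.2)
  }
})
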