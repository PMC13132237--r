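test_that("feature-group construction is a deterministic product", {
  g <- build_feature_groups("bp_alpha", rois = c("left_motor", "central",
                                                 "whole_scalp"),
                            transformations = c("normalization",
                                                "log_distance_to_median"))
  expect_length(g, 6)
  expect_equal(format(g[[1]]), "bp_alpha|left_motor|normalization")
  expect_length(build_feature_groups(character(0)), 0)
  expect_error(build_feature_groups("x", transformations = "rank"),
               "unknown transformation")
})

test_that("group matrices select ROI channels and optional columns", {
  chans <- c(left_motor_channels(), "Cz", "Pz")
  ft <- data.frame(session_id = "a", subject_id = "s", cohort = 1,
                   visit = "retest")
  for (ch in chans) ft[[paste0("bp_alpha_", ch)]] <- rnorm(1)
  ft$pre_rqs <- 0.5
  roi_map <- roi_definitions(chans)
  g <- build_feature_groups("bp_alpha", rois = "left_motor",
                            transformations = "none")[[1]]
  X <- group_matrix(g, ft, roi_map)
  expect_equal(sort(colnames(X)),
               sort(paste0("bp_alpha_", left_motor_channels())))
  g2 <- build_feature_groups("bp_alpha", rois = "left_motor",
                             transformations = "none",
                             include_pretbs = TRUE,
                             include_visit_type = TRUE)[[1]]
  X2 <- group_matrix(g2, ft, roi_map)
  expect_equal(ncol(X2), 6 + 1 + 1)  # roi + pre_rqs + visit_type
  expect_equal(unname(X2[, "visit_type"]), 1)
  expect_error(group_matrix(
    build_feature_groups("nope", rois = "left_motor",
                         transformations = "none")[[1]], ft, roi_map),
    "matches no columns")
  g3 <- g; g3$roi <- "occipital"
  expect_error(group_matrix(g3, ft, roi_map), "unknown ROI")
})

test_that("transformations are fit on the training matrix only", {
  set.seed(10)
  tr <- matrix(rnorm(60, 5, 2), 20, 3,
               dimnames = list(NULL, c("a", "b", "c")))
  ev <- matrix(rnorm(30, 100, 50), 10, 3,
               dimnames = list(NULL, c("a", "b", "c")))
  z <- apply_transformation(tr, ev, "normalization")
  expect_equal(unname(colMeans(z$train)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(z$train, 2, sd)), rep(1, 3),
               tolerance = 1e-12)
  # train output unchanged when the eval matrix changes: no leakage
  z2 <- apply_transformation(tr, ev * 1000, "normalization")
  expect_identical(z$train, z2$train)
  # log distance: value at the train median maps to log(eps)
  tr2 <- matrix(c(1, 2, 3, 4, 5), 5, 1, dimnames = list(NULL, "a"))
  ld <- apply_transformation(tr2, matrix(3, 1, 1,
                                         dimnames = list(NULL, "a")),
                             "log_distance_to_median")
  expect_equal(unname(ld$eval[1, 1]), log(1e-6))
  # zero-variance feature dropped with warning
  trz <- cbind(tr, flat = 1)
  expect_warning(z3 <- apply_transformation(trz, cbind(ev, flat = 1),
                                            "normalization"),
                 "zero-variance")
  expect_false("flat" %in% colnames(z3$train))
})

test_that("cross-validation is deterministic and calibrated at chance", {
  set.seed(20)
  X <- matrix(rnorm(160), 80, 2, dimnames = list(NULL, c("f1", "f2")))
  y <- rep(c("positive", "negative"), 40)
  cv1 <- cross_validate("lda_ledoit_wolf", X, y, reps = 3, seed = 7)
  cv2 <- cross_validate("lda_ledoit_wolf", X, y, reps = 3, seed = 7)
  expect_identical(cv1$per_fold, cv2$per_fold)
  expect_equal(nrow(cv1$per_fold), 15)
  # random labels: chance-level ROC-AUC
  expect_lt(abs(cv1$mean["roc_auc"] - 0.5), 0.1)
  # CI contains the mean
  expect_true(all(cv1$ci_half >= 0, na.rm = TRUE))
  expect_error(cross_validate("lda_oas", X[1:6, ], y[1:6], folds = 5),
               "stratify")
})

test_that("the CV confidence interval shrinks with more repetitions", {
  set.seed(23)
  n <- 100
  y <- rep(c("positive", "negative"), each = n / 2)
  X <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "f"))
  X[y == "positive", 1] <- X[y == "positive", 1] + 1
  cv2 <- cross_validate("lda_oas", X, y, reps = 2, seed = 5)
  cv8 <- cross_validate("lda_oas", X, y, reps = 8, seed = 5)
  ratio <- cv2$ci_half["roc_auc"] / cv8$ci_half["roc_auc"]
  expect_gt(unname(ratio), 1.2)  # ~2 expected for 4x the repetitions
  expect_lt(unname(ratio), 3.5)
})

test_that("all nine classifiers train, score and separate planted signal", {
  set.seed(21)
  n <- 120
  y <- rep(c("positive", "negative"), each = n / 2)
  X <- matrix(rnorm(n * 3), n, 3,
              dimnames = list(NULL, c("s1", "s2", "noise")))
  X[y == "positive", 1:2] <- X[y == "positive", 1:2] + 1.5
  for (id in classifier_ids()) {
    model <- fit_classifier(id, X, y, seed = 3)
    sc <- score_classifier(model, X)
    expect_length(sc, n)
    expect_gt(roc_auc(y, sc), 0.75)
    pred <- predict_classifier(model, X)
    expect_true(all(pred %in% c("positive", "negative")))
  }
})

test_that("model selection applies the admissibility rule and tie-breaks", {
  cand <- function(id, auc, sens, spec, nf) {
    list(id = id, n_features = nf,
         cv = list(mean = c(roc_auc = auc, sensitivity = sens,
                            specificity = spec)))
  }
  # top AUC but inadmissible specificity is excluded
  sel <- select_model(list(cand("a", 0.9, 0.8, 0.55, 3),
                           cand("b", 0.7, 0.7, 0.7, 3)))
  expect_equal(sel$id, "b")
  # equal AUC: fewer features wins
  sel2 <- select_model(list(cand("big", 0.8, 0.7, 0.7, 10),
                            cand("small", 0.8, 0.7, 0.7, 2)))
  expect_equal(sel2$id, "small")
  # equal AUC and size: lexicographic id
  sel3 <- select_model(list(cand("zeta", 0.8, 0.7, 0.7, 2),
                            cand("alpha", 0.8, 0.7, 0.7, 2)))
  expect_equal(sel3$id, "alpha")
  # everything excluded
  out <- select_model(list(cand("a", 0.9, 0.5, 0.9, 1)))
  expect_s3_class(out, "no_admissible_model")
  expect_error(select_model(list()), "no candidates")
})

test_that("external validation: separable data, bootstrap, subject guard", {
  set.seed(22)
  n <- 60
  y <- rep(c("positive", "negative"), each = n / 2)
  X <- matrix(c(ifelse(y == "positive", 5, -5) + rnorm(n, sd = 0.1)),
              ncol = 1, dimnames = list(NULL, "f"))
  v <- external_validate("lda_oas", X, y, X, y, n_boot = 200, seed = 4)
  expect_true(all(v$point == 1))
  expect_true(all(v$ci[1, ] == 1))
  expect_equal(unname(v$chance["roc_auc"]), 0.5)
  expect_equal(unname(v$chance["accuracy"]), 0.5)
  expect_error(external_validate("lda_oas", X, y, X, y,
                                 subjects_train = c("s1", "s2"),
                                 subjects_ext = c("s2", "s3")),
               "both training and external")
  # bootstrap CI of random scores covers chance most of the time
  hits <- 0
  for (seed in 1:10) {
    set.seed(seed)
    Xr <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "f"))
    vr <- external_validate("gnb_empirical", Xr, y,
                            matrix(rnorm(n), ncol = 1,
                                   dimnames = list(NULL, "f")), y,
                            n_boot = 300, seed = seed)
    if (vr$ci[1, "roc_auc"] <= 0.5 && vr$ci[2, "roc_auc"] >= 0.5)
      hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("experiment designs split sessions as specified", {
  cfg <- traits_config(80, seed = 51)
  cfg$n_subjects_per_cohort <- c(40L, 40L)
  rec <- generate_cohorts(cfg)
  ft <- planted_feature_table(rec)
  gt <- ground_truth_labels(rec)
  labs <- list(planted = gt[, c("session_id", "label")])
  base_cfg <- list(families = "planted_trait", rois = "whole_scalp",
                   transformations = "none",
                   classifiers = "lda_ledoit_wolf", reps = 2L,
                   n_boot = 50L, seed = 3L)
  cs <- run_experiment("cross_session", ft, labs, base_cfg)
  expect_setequal(cs$train_sessions,
                  ft$session_id[ft$visit == "initial"])
  cc <- run_experiment("cross_cohort", ft, labs, base_cfg)
  expect_setequal(cc$train_sessions, ft$session_id[ft$cohort == 1])
  # visit type appended exactly once in cross-cohort
  expect_equal(cc$selected$n_features, 2)
  expect_equal(cs$selected$n_features, 1)
  xs <- run_experiment("cross_subject", ft, labs, base_cfg)
  tr_subj <- unique(ft$subject_id[ft$session_id %in% xs$train_sessions])
  ex_subj <- unique(ft$subject_id[ft$session_id %in%
                                    xs$external_sessions])
  expect_length(intersect(tr_subj, ex_subj), 0)
})
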