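test_that("MEP labelling: direction-blind t-test with inclusive boundary", {
  set.seed(1)
  pre <- rnorm(150, 1.0, 0.1)
  post <- rnorm(150, 1.5, 0.1)
  r <- mep_label(pre, post)
  expect_lt(r$p, 1e-6)
  expect_equal(r$label, "positive")
  # identical distributions: non-responder
  expect_equal(mep_label(pre, pre)$label, "negative")
  # two-tailed: symmetric under swapping pre and post
  expect_equal(mep_label(pre, post)$p, mep_label(post, pre)$p)
  # suppression also counts as response
  expect_equal(mep_label(post, pre)$label, "positive")
  # degenerate zero-variance blocks
  expect_equal(mep_label(rep(1, 5), rep(1, 5))$p, 1)
  expect_error(mep_label(1, c(1, 2)), "at least 2")
})

test_that("the p <= alpha boundary is inclusive", {
  # engineer p exactly at alpha via the labelling rule itself
  r <- mep_label(c(1, 2, 3, 4), c(1.2, 2.2, 3.2, 4.2), alpha = 1)
  expect_equal(r$label, "positive")  # p <= 1 always
  # construct a near-boundary case and check rule consistency
  set.seed(2)
  pre <- rnorm(20); post <- rnorm(20, 0.5)
  r <- mep_label(pre, post, alpha = 0.05)
  expect_equal(r$label, if (r$p <= 0.05) "positive" else "negative")
})

test_that("LMFP ratio equals the oracle chain and is scale-equivariant", {
  t <- seq(0, 200, by = 4)
  base <- matrix(rep(tbsdrift:::tep_template(t) + 3, each = 6), 6,
                 dimnames = list(left_motor_channels(), t))
  pre <- tep_array(base, 3, noise_sd = 0.2, seed = 3)
  post <- tep_array(base, 3, noise_sd = 0.2, seed = 4)
  w <- tep_window(25, 145)
  r <- lmfp_ratio(pre, post, w = w, t = t)
  oracle <- mean(sapply(1:3, function(i) {
    v <- oracle_lmfp(post[i, , ], left_motor_channels(), t)
    curve <- structure(list(t = t, value = v, K = 6,
                            roi = left_motor_channels()),
                       class = "lmfp_curve")
    window_auc(curve, w)
  })) / mean(sapply(1:3, function(i) {
    v <- oracle_lmfp(pre[i, , ], left_motor_channels(), t)
    curve <- structure(list(t = t, value = v, K = 6,
                            roi = left_motor_channels()),
                       class = "lmfp_curve")
    window_auc(curve, w)
  }))
  expect_lt(abs(r$ratio - oracle), 1e-12)
  # homogeneity: halving the post waveforms halves the ratio
  r_half <- lmfp_ratio(pre, post * 0.5, w = w, t = t)
  expect_equal(r_half$ratio, r$ratio * 0.5, tolerance = 1e-12)
  expect_equal(r_half$label, "negative")
  # ratio exactly 1 is facilitation (boundary inclusive)
  r_same <- lmfp_ratio(pre, pre, w = w, t = t)
  expect_equal(r_same$ratio, 1)
  expect_equal(r_same$label, "positive")
  zero <- tep_array(base * 0, 2, noise_sd = 0)
  expect_error(lmfp_ratio(zero, post, w = w, t = t), "undefined")
})

test_that("window construction: sweep arithmetic, defaults, errors", {
  sweep_only <- make_windows(apriori = list(), sweep_span = c(25, 345),
                             sweep_step = 30)
  expect_length(sweep_only, 11)
  expect_equal(sapply(sweep_only[1:3], `[[`, "start_ms"), c(25, 55, 85))
  expect_equal(sweep_only[[11]]$end_ms, 345)
  full <- make_windows()
  expect_length(full, 43)
  keys <- sapply(full, format)
  expect_true(all(c("100-131ms", "85-115ms") %in% keys))
  expect_false(any(duplicated(keys)))
  expect_error(make_windows(apriori = list(), sweep_span = NULL), "empty")
  expect_error(make_windows(coverage = c(0, 200)), "coverage")
})

test_that("label_all is complete, deterministic and order-invariant", {
  cfg <- tiny_config(seed = 77)
  rec <- generate_cohorts(cfg)
  m <- categorization_method("lmfp_window", tep_window(100, 131))
  l1 <- label_all(rec, m)
  l2 <- label_all(rev(rec), m)
  expect_setequal(l1$session_id, l2$session_id)
  o1 <- l1[order(l1$session_id), ]
  o2 <- l2[order(l2$session_id), ]
  expect_equal(o1$label, o2$label)
  expect_equal(o1$diagnostic, o2$diagnostic)
  expect_false(anyNA(l1$diagnostic))
  # positivity rule agrees with the diagnostics
  expect_equal(l1$label, ifelse(l1$diagnostic >= 1, "positive",
                                "negative"))
  mm <- categorization_method("mep_t25")
  lm <- label_all(rec, mm)
  expect_equal(lm$label, ifelse(lm$diagnostic <= 0.05, "positive",
                                "negative"))
})

test_that("planted facilitation fraction is recovered by LMFP labels", {
  cfg <- tiny_config(seed = 101, n_subjects_per_cohort = c(200L, 0L),
                     initial_only = c(200L, 0L), retest_only = c(0L, 0L),
                     n_epochs = 1L, positive_rate = 0.7,
                     mep_params = list(meanlog = log(800), sdlog = 0.5,
                                       modulation = 0.4,
                                       n_trials = list(c(pre = 8, T5 = 8,
                                                         T25 = 4))))
  rec <- generate_cohorts(cfg)
  lab <- label_all(rec, categorization_method("lmfp_window",
                                              tep_window(100, 131)))
  expect_lt(abs(mean(lab$label == "positive") - 0.7), 0.07)
})
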