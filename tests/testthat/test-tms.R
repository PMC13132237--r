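test_that("LMFP dispersion formula: zero, unit and random cases", {
  t <- 0:9
  eq <- matrix(5, 3, 10, dimnames = list(c("C1", "C3", "C5"), NULL))
  expect_true(all(lmfp_curve(eq, roi = c("C1", "C3", "C5"),
                             t = t)$value == 0))
  two <- rbind(C1 = rep(1, 10), C3 = rep(-1, 10))
  expect_equal(lmfp_curve(two, roi = c("C1", "C3"), t = t)$value,
               rep(1, 10))
  set.seed(5)
  six <- matrix(rnorm(60), 6, 10,
                dimnames = list(left_motor_channels(), NULL))
  got <- lmfp_curve(six, t = t)
  expect_lt(max(abs(got$value -
                      oracle_lmfp(six, left_motor_channels(), t))),
            1e-12)
  expect_error(lmfp_curve(six[1:5, ], t = t), "FC5")
})

test_that("LMFP is invariant to a common offset (re-referencing)", {
  set.seed(6)
  six <- matrix(rnorm(60), 6, 10,
                dimnames = list(left_motor_channels(), NULL))
  shifted <- six + 42
  expect_equal(lmfp_curve(six, t = 0:9)$value,
               lmfp_curve(shifted, t = 0:9)$value, tolerance = 1e-9)
})

test_that("window AUC: Simpson exactness, constants, additivity", {
  t <- seq(0, 60, by = 1)
  const <- structure(list(t = t, value = rep(4, length(t)), K = 1,
                          roi = "C1"), class = "lmfp_curve")
  expect_equal(window_auc(const, tep_window(10, 40)), 4 * 30)
  # Simpson is exact on quadratics (odd sample count)
  quad <- structure(list(t = t, value = 3 * t^2 - 2 * t + 1, K = 1,
                         roi = "C1"), class = "lmfp_curve")
  exact <- function(a, b) (b^3 - a^3) - (b^2 - a^2) + (b - a)
  expect_lt(abs(window_auc(quad, tep_window(0, 60)) - exact(0, 60)), 1e-9)
  # additive over abutting windows
  set.seed(7)
  wig <- structure(list(t = t, value = abs(rnorm(length(t))), K = 1,
                        roi = "C1"), class = "lmfp_curve")
  expect_equal(window_auc(wig, tep_window(0, 30)) +
                 window_auc(wig, tep_window(30, 60)),
               window_auc(wig, tep_window(0, 60)), tolerance = 1e-12)
  expect_error(window_auc(const, tep_window(10, 11.5)), "fewer than 3")
})

test_that("block AUC averages per-trial AUCs and matches a naive loop", {
  t <- seq(0, 100, by = 2)
  base <- matrix(rnorm(6 * length(t)), 6,
                 dimnames = list(left_motor_channels(), t))
  blk <- tep_array(abs(base) + 1, n_trials = 4, noise_sd = 0.3, seed = 8)
  w <- tep_window(10, 90)
  naive <- mean(sapply(1:4, function(i)
    window_auc(lmfp_curve(blk[i, , ], t = t), w)))
  expect_lt(abs(block_lmfp_auc(blk, w = w, t = t) - naive), 1e-12)
  # identical trials equal the single-trial value
  blk0 <- tep_array(abs(base) + 1, n_trials = 3, noise_sd = 0)
  expect_equal(block_lmfp_auc(blk0, w = w, t = t),
               window_auc(lmfp_curve(blk0[1, , ], t = t), w))
})

test_that("regression quality score spans its range as SNR varies", {
  t <- seq(0, 300, by = 5)
  template <- matrix(rep(tbsdrift:::tep_template(t), each = 6), 6,
                     dimnames = list(left_motor_channels(), t))
  # identical non-constant trials: perfect consistency
  clean <- tep_array(template, n_trials = 5, noise_sd = 0)
  expect_equal(rqs(clean, t = t), 1)
  # independent noise: near zero
  noise <- tep_array(matrix(0, 6, length(t),
                            dimnames = dimnames(template)),
                     n_trials = 50, noise_sd = 3, seed = 9)
  expect_lt(rqs(noise, t = t), 0.1)
  # monotone in SNR
  noisy_sig <- tep_array(template, n_trials = 50, noise_sd = 3, seed = 9)
  expect_gt(rqs(noisy_sig, t = t), rqs(noise, t = t))
  expect_true(rqs(noisy_sig, t = t) >= 0 && rqs(noisy_sig, t = t) <= 1)
})

test_that("baseline features honour the experiment mode", {
  t <- seq(0, 300, by = 5)
  base <- matrix(rep(tbsdrift:::tep_template(t), each = 6), 6,
                 dimnames = list(left_motor_channels(), t))
  tep <- tep_array(base + 2, n_trials = 4, noise_sd = 0.5, seed = 10)
  s <- manual_session(mep = list(pre = c(1, 2, 3)),
                      tep = list(pre = tep), tep_time = t)
  mep_feats <- baseline_features(s, "mep_experiment")
  expect_named(mep_feats, c("pre_mep_mean", "pre_mep_sd",
                            "pre_lmfp_auc_15_80", "pre_rqs"))
  expect_equal(unname(mep_feats["pre_mep_mean"]), 2)
  expect_equal(unname(mep_feats["pre_mep_sd"]), 1)
  lmfp_feats <- baseline_features(s, "lmfp_experiment")
  expect_length(lmfp_feats, 2)
  # componentwise agreement with the direct chain
  expect_equal(unname(mep_feats["pre_lmfp_auc_15_80"]),
               block_lmfp_auc(tep, w = tep_window(15, 80), t = t))
  expect_equal(unname(mep_feats["pre_rqs"]), rqs(tep, t = t))
  s_nopre <- manual_session(mep = list(pre = c(1, 2)), tep = list(),
                            tep_time = t)
  expect_error(baseline_features(s_nopre, "lmfp_experiment"), "pre-TBS")
})
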