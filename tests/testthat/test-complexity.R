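test_that("degenerate series give the expected entropy values", {
  # single ordinal pattern in a monotone series
  expect_equal(single_scale_entropy(1:50, entropy_spec("permutation",
                                                       m = 3)), 0)
  # constant series: sample entropy returns 0 with a note
  expect_message(
    v <- single_scale_entropy(rep(1, 100), entropy_spec("sample")),
    "constant")
  expect_equal(v, 0)
  # coarse-graining of a constant series stays degenerate at every scale
  ms <- multiscale_spec("coarse_graining",
                        entropy_spec("permutation", m = 2), scales = 3)
  expect_equal(suppressMessages(multiscale_curve(rep(2, 200), ms))$values,
               rep(0, 3))
})

test_that("series preconditions are enforced", {
  expect_error(single_scale_entropy(rnorm(15), entropy_spec("sample")),
               "too short")
  expect_error(single_scale_entropy(c(rnorm(99), NA),
                                    entropy_spec("sample")),
               "non-finite")
  ms <- multiscale_spec("coarse_graining", entropy_spec("sample"),
                        scales = 10)
  expect_error(multiscale_curve(rnorm(100), ms), "scale")
})

test_that("sample entropy on a short periodic series matches the direct
           template count", {
  x <- rep(c(1, 2, 3), 10)
  got <- single_scale_entropy(x, entropy_spec("sample", m = 2))
  expect_entropy_equal(got, oracle_sampen(x, 2))
})

test_that("permutation entropy of uniform noise approaches log(m!)", {
  set.seed(7)
  x <- runif(1e4)
  h <- single_scale_entropy(x, entropy_spec("permutation", m = 3))
  expect_lt(abs(h / log(factorial(3)) - 1), 0.01)
})

test_that("every measure matches its brute-force oracle on random series", {
  set.seed(11)
  specs <- default_entropy_battery(scales = 5)
  for (i in 1:5) {
    x <- rnorm(120 + 10 * i)
    for (sp in specs$single)
      expect_entropy_equal(single_scale_entropy(x, sp),
                           oracle_single(x, sp))
  }
})

test_that("multiscale procedures match the oracle and agree at scale 1", {
  set.seed(13)
  x <- rnorm(400)
  base <- entropy_spec("sample", m = 2)
  for (proc in c("coarse_graining", "time_shifted", "composite")) {
    ms <- multiscale_spec(proc, base, scales = 4)
    cur <- multiscale_curve(x, ms)
    expect_equal(cur$values[1], single_scale_entropy(x, base))
    for (s in 1:4)
      expect_entropy_equal(cur$values[s],
                           oracle_multiscale(x, proc, base, s))
  }
})

test_that("entropies are invariant to positive affine rescaling", {
  set.seed(17)
  x <- rnorm(300)
  y <- 3.7 * x + 11
  for (sp in default_entropy_battery()$single) {
    a <- single_scale_entropy(x, sp)
    b <- single_scale_entropy(y, sp)
    expect_equal(a, b, tolerance = 1e-9, label = sp$measure)
  }
})

test_that("complexity index is the trapezoid AUC and is linear", {
  expect_equal(complexity_index(rep(3, 20)), 19 * 3)
  expect_equal(complexity_index(1:20), 199.5)
  expect_equal(complexity_index(rep(0, 20)), 0)
  set.seed(19)
  c1 <- runif(20); c2 <- runif(20)
  expect_equal(complexity_index(2 * c1 + 5 * c2),
               2 * complexity_index(c1) + 5 * complexity_index(c2))
})

test_that("session complexity features are deterministic and complete", {
  battery <- list(single = list(entropy_spec("permutation", m = 3),
                                entropy_spec("lempel_ziv")),
                  multiscale = list(
                    multiscale_spec("coarse_graining",
                                    entropy_spec("permutation", m = 2),
                                    scales = 5)))
  set.seed(23)
  rs <- array(rnorm(6 * 2 * 500), dim = c(6, 2, 500),
              dimnames = list(NULL, c("C1", "C3"), NULL))
  s1 <- manual_session(rs = rs, fs = 50)
  s2 <- manual_session(rs = rs, fs = 50, id = "s2_initial")
  f1 <- session_complexity_features(s1, battery)
  f2 <- session_complexity_features(s2, battery)
  expect_equal(f1$value, f2$value)  # same data, same features
  # |single| + |multiscale| features per channel
  expect_equal(nrow(f1), 2 * 3)
  expect_error(session_complexity_features(
    manual_session(rs = rs[1:3, , , drop = FALSE], fs = 50), battery),
    "epochs")
})

test_that("broadband noise has higher scale-1 sample entropy than a
           near-periodic signal", {
  set.seed(29)
  noisy <- rnorm(1000)
  tone <- sin(2 * pi * 0.05 * (1:1000)) + 0.05 * rnorm(1000)
  sp <- entropy_spec("sample")
  expect_gt(single_scale_entropy(noisy, sp),
            single_scale_entropy(tone, sp))
})
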