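test_that("a constant red reference leaves the green trace untouched", {
  g <- region_trace(5 + sin(seq(0, 60, length.out = 600)), 10)
  r <- region_trace(rep(3, 600), 10)
  out <- motion_correct(g, r)
  expect_equal(out$values, g$values, tolerance = 1e-12)
  expect_equal(out$stage_label, "motion_corrected")
})

test_that("common-mode artifacts cancel in the ratio", {
  set.seed(1)
  clean <- 4 + 0.5 * sin(seq(0, 60, length.out = 600))
  m <- 1 + 0.2 * sin(seq(0, 7, length.out = 600))   # shared motion trace
  g <- region_trace(clean * m, 10)
  r <- region_trace(2 * m, 10)
  out <- motion_correct(g, r)
  # the artifact cancels exactly; the output equals the clean trace up to the
  # median-of-red rescaling, which dF/F later removes
  expect_equal(out$values / stats::median(out$values),
               clean / stats::median(clean), tolerance = 1e-10)
  expect_lt(stats::sd(out$values / clean), 1e-12)
})

test_that("motion correction recovers the artifact-free coefficients on synthetic data", {
  cfg <- sim_config(duration_s = 300, motion_amplitude = 0.1, n_motion_events = 8,
                    bleach_tau_s = Inf, noise_sd = 0, red_noise_sd = 0, seed = 21)
  s <- quietly(simulate_session(cfg))
  u <- quietly(unmix_session(s$frames$region1, s$refs))
  clean <- s$truth$coeff_clean$region1["gcamp", ]
  raw_rms <- sqrt(mean((u$coeff["gcamp", ] - clean)^2))
  corr <- quietly(motion_correct(coeff_trace(u, "gcamp"), coeff_trace(u, "tdtomato")))
  corr_rms <- sqrt(mean((corr$values - clean)^2))
  expect_lt(corr_rms, 0.2 * raw_rms)  # >= 80% RMS reduction
})

test_that("a mostly non-positive red reference is a data-quality error", {
  g <- region_trace(rep(1, 100), 10)
  r <- region_trace(c(rep(-1, 20), rep(2, 80)), 10)
  expect_error(motion_correct(g, r), "data-quality")
})

test_that("low-red frames are masked and interpolated", {
  g <- region_trace(rep(2, 400), 10)
  red <- rep(2, 400); red[100:102] <- 0.01
  out <- quietly(motion_correct(g, region_trace(red, 10)))
  expect_equal(attr(out, "n_masked"), 3L)
  expect_true(all(is.finite(out$values)))
  expect_equal(out$values[100:102], rep(2, 3), tolerance = 1e-9)
})

test_that("high-pass removes DC exactly and passes the band", {
  const <- region_trace(rep(7, 600), 10, "motion_corrected")
  out <- highpass_bleach_correct(const)
  expect_equal(out$values, rep(7, 600), tolerance = 1e-5)
  expect_lt(stats::sd(out$values), 1e-6)  # fluctuation removed entirely

  t <- (0:5999) / 10
  sine <- region_trace(10 + sin(2 * pi * 0.3 * t), 10, "motion_corrected")
  hp <- highpass_bleach_correct(sine)
  expect_equal(stats::sd(hp$values) / stats::sd(sine$values - 10), 1,
               tolerance = 0.05)  # passband flatness at 0.3 Hz
})

test_that("bleach is removed while in-band structure survives", {
  t <- (0:5999) / 10
  sinus <- 0.2 * sin(2 * pi * 0.3 * t)
  tr <- region_trace(1 + exp(-t / 300) + sinus, 10, "motion_corrected")
  hp <- highpass_bleach_correct(tr)
  expect_gt(cor(hp$values, sinus), 0.95)
  # sub-cutoff power attenuated by >= 20 dB
  slow <- region_trace(1 + sin(2 * pi * 0.04 * t), 10, "motion_corrected")
  hs <- highpass_bleach_correct(slow)
  atten_db <- 20 * log10(stats::sd(hs$values) / stats::sd(slow$values))
  expect_lt(atten_db, -20)
})

test_that("high-pass is idempotent in the passband", {
  t <- (0:2999) / 10
  x <- region_trace(5 + sin(2 * pi * 0.3 * t) + 0.5 * sin(2 * pi * 0.7 * t),
                    10, "motion_corrected")
  once <- highpass_bleach_correct(x)
  twice <- highpass_bleach_correct(region_trace(once$values, 10, "motion_corrected"))
  rms1 <- sqrt(mean((once$values - stats::median(once$values))^2))
  rms2 <- sqrt(mean((twice$values - stats::median(twice$values))^2))
  expect_lt(abs(rms2 - rms1) / rms1, 0.01)
})

test_that("traces shorter than the filter warm-up are rejected", {
  expect_error(highpass_bleach_correct(region_trace(rnorm(100), 10, "motion_corrected")),
               "need >= 30 s")
})

test_that("dF/F follows the median definition", {
  expect_equal(compute_dff(region_trace(rep(3, 50), 10, "highpassed"))$values,
               rep(0, 50))
  out <- compute_dff(region_trace(c(1, 1, 1, 3), 2, "highpassed"))
  expect_equal(out$values, c(0, 0, 0, 2))
  expect_error(compute_dff(region_trace(c(-2, -1, 0, 1), 10, "highpassed")),
               "undefined")
})

test_that("dF/F is invariant to positive rescaling and has zero median", {
  set.seed(9)
  for (i in 1:5) {
    f <- region_trace(2 + abs(rnorm(200)), 10, "highpassed")
    scaled <- region_trace(runif(1, 0.1, 10) * f$values, 10, "highpassed")
    expect_equal(compute_dff(f)$values, compute_dff(scaled)$values,
                 tolerance = 1e-12)
    expect_equal(stats::median(compute_dff(f)$values), 0)
  }
})

test_that("noiseless end-to-end preprocessing recovers ground-truth dF/F", {
  cfg <- sim_config(duration_s = 300, noise_sd = 0, red_noise_sd = 0,
                    bleach_tau_s = 300, motion_amplitude = 0.1,
                    n_motion_events = 6, seed = 31)
  s <- quietly(simulate_session(cfg))
  u <- quietly(unmix_session(s$frames$region1, s$refs))
  dff <- quietly(preprocess_traces(u))
  # ground-truth pathway: the same dF/F definition applied to the
  # artifact-free coefficients, isolating artifact-removal fidelity
  clean <- region_trace(s$truth$coeff_clean$region1["gcamp", ], 10,
                        "motion_corrected")
  gt_dff <- compute_dff(highpass_bleach_correct(clean))
  expect_gt(cor(dff$values, gt_dff$values), 0.99)
})
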