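test_that("reference spectra are unimodal, distinct and max-normalized", {
  cfg <- sim_config(wavelength_nm = seq(480, 650, by = 2))
  refs <- generate_reference_spectra(cfg)
  for (f in refs$fluorophores) {
    curve <- refs$curves[f, ]
    expect_equal(max(curve), 1)
    expect_true(all(curve >= 0))
    # exactly one interior local maximum
    d <- diff(curve)
    expect_equal(sum(d[-length(d)] > 0 & d[-1] <= 0), 1)
  }
  peaks <- refs$wavelength_nm[apply(refs$curves, 1, which.max)]
  expect_lt(abs(peaks[1] - cfg$emission_peaks_nm["gcamp"]), 4)
  expect_lt(abs(peaks[2] - cfg$emission_peaks_nm["tdtomato"]), 4)
  expect_lt(cor(refs$curves[1, ], refs$curves[2, ]), 0.9)
  expect_true(is.finite(attr(refs, "condition_number")))
})

test_that("degenerate spectral configurations are rejected", {
  cfg <- sim_config()
  cfg$emission_peaks_nm <- c(gcamp = 550, tdtomato = 550)
  expect_error(generate_reference_spectra(cfg), "unidentifiable")
  cfg2 <- sim_config(wavelength_nm = seq(520, 560, length.out = 21))
  expect_error(generate_reference_spectra(cfg2), "too narrow")
})

test_that("sim_config validates the acquisition geometry", {
  expect_error(sim_config(frame_rate_hz = 0.8), "frame_rate")
  expect_error(sim_config(duration_s = 10.05), "integer frame count")
  expect_error(sim_config(rho_band_target = 0.99), "rho_band_target")
  expect_error(sim_config(wavelength_nm = seq(500, 520, 2)), "16 bins")
})

test_that("identical config and seed give bit-identical sessions", {
  cfg <- test_config()
  s1 <- quietly(simulate_session(cfg))
  s2 <- quietly(simulate_session(cfg))
  expect_identical(s1$calcium$region1$values, s2$calcium$region1$values)
  expect_identical(s1$frames$region1$intensity, s2$frames$region1$intensity)
  expect_identical(s1$events, s2$events)
})

test_that("latent band correlation hits its target", {
  # independence case: sample r near 0 over a 600 s session
  c0 <- sim_config(duration_s = 600, rho_band_target = 0, n_bouts = 0, seed = 11)
  expect_lt(abs(truth_band_r(simulate_two_region_calcium(c0)$truth)), 0.1)
  # strong-coupling case, checked against the direct Pearson oracle
  c9 <- sim_config(duration_s = 600, rho_band_target = 0.9, n_bouts = 0, seed = 12)
  tr <- simulate_two_region_calcium(c9)$truth
  expect_lt(abs(truth_band_r(tr) - 0.9), 0.07)
  # negative targets flip the sign of the shared part
  cn <- sim_config(duration_s = 600, rho_band_target = -0.6, n_bouts = 0, seed = 13)
  expect_lt(abs(truth_band_r(simulate_two_region_calcium(cn)$truth) + 0.6), 0.1)
  expect_error(simulate_two_region_calcium(sim_config(rho_band_target = 0.995)),
               "rho_band_target")
})

test_that("mean recovered latent correlation is calibrated over seeds", {
  rs <- vapply(1:12, function(s) {
    cfg <- sim_config(duration_s = 600, rho_band_target = 0.6, n_bouts = 0, seed = s)
    truth_band_r(simulate_two_region_calcium(cfg)$truth)
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.6), 0.03)
})

test_that("behavior schedules respect gaps, margins and feasibility", {
  cfg <- sim_config(duration_s = 300, n_bouts = 10, seed = 2)
  set.seed(2)
  ev <- simulate_behavior_schedule(cfg)
  expect_equal(nrow(ev), 10)
  expect_true(all(ev$onset_s[-1] - ev$offset_s[-10] >= 6 - 1e-9))
  expect_true(all(ev$onset_s >= 3) && all(ev$offset_s <= 300 - 3))
  expect_error(simulate_behavior_schedule(sim_config(duration_s = 300, n_bouts = 100)),
               "configuration error")
})

test_that("a 3:1 exploration-time schedule scores a discrimination ratio of 0.5", {
  cfg <- sim_config(duration_s = 600, n_bouts = 10, phase = "retrieval", seed = 5)
  set.seed(5)
  ev <- simulate_behavior_schedule(cfg, novel_time_ratio = 3)
  dr <- discrimination_ratio(ev, "retrieval")
  expect_equal(dr$ratio, 0.5)
})

test_that("noiseless frames are exact linear combinations of the references", {
  cfg <- test_config(noise_sd = 0, motion_amplitude = 0, bleach_tau_s = Inf)
  s <- quietly(simulate_session(cfg))
  refs <- s$refs
  X <- t(refs$curves)
  # residual of projecting each frame onto the reference plane is zero
  fit <- X %*% qr.coef(qr(X), t(s$frames$region1$intensity))
  expect_lt(max(abs(fit - t(s$frames$region1$intensity))), 1e-10)
  expect_equal(unname(s$truth$clip_fraction["region1"]), 0)
})

test_that("rendered bleach decays with the configured time constant", {
  # constant coefficients, no motion, no noise: total intensity is a clean
  # exponential whose log-linear fit recovers tau within 5%
  cfg <- sim_config(duration_s = 300, noise_sd = 0, motion_amplitude = 0,
                    bleach_tau_s = 300, n_bouts = 0, ca_noise_sd = 0,
                    green_gain = 0, seed = 3)
  s <- quietly(simulate_session(cfg))
  tot <- rowSums(s$frames$region1$intensity)
  t <- s$frames$region1$time_s
  tau_fit <- -1 / stats::coef(stats::lm(log(tot) ~ t))[2]
  expect_lt(abs(tau_fit - 300) / 300, 0.05)
})

test_that("motion pulses are common mode across fluorophores", {
  cfg <- sim_config(duration_s = 120, noise_sd = 0, red_noise_sd = 0,
                    bleach_tau_s = Inf, motion_amplitude = 0.1,
                    n_motion_events = 1, n_bouts = 0, ca_noise_sd = 0,
                    green_gain = 0, seed = 8)
  s <- quietly(simulate_session(cfg))
  u <- quietly(unmix_session(s$frames$region1, s$refs))
  rel_g <- u$coeff["gcamp", ] / cfg$green_baseline
  rel_r <- u$coeff["tdtomato", ] / cfg$red_level
  # both fluorophores' fitted coefficients move by the same relative amount
  expect_lt(max(abs(rel_g - rel_r)), 1e-8)
  expect_gt(max(rel_g) - 1, 0.05)  # the pulse is actually present
})

test_that("ground-truth invariants hold", {
  s <- quietly(simulate_session(test_config()))
  expect_true(all(s$truth$coeff_true$region1 >= 0))
  expect_true(all(s$truth$motion_trace > 0))
  m <- 3
  expect_true(all(s$truth$event_schedule$onset_s >= m))
  expect_true(all(s$truth$event_schedule$offset_s <= s$config$duration_s - m))
})
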