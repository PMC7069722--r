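refs <- generate_reference_spectra(sim_config())

test_that("an exact member of the model space is recovered exactly", {
  sp <- 1.0 * refs$curves["gcamp", ] + 0.0 * refs$curves["tdtomato", ]
  fit <- unmix_frame(sp, refs)
  expect_equal(unname(fit$coefficients), c(1, 0), tolerance = 1e-12)
  expect_lt(fit$residual_rms, 1e-12)
})

test_that("the all-zero spectrum yields zero coefficients", {
  fit <- unmix_frame(rep(0, length(refs$wavelength_nm)), refs)
  expect_equal(unname(fit$coefficients), c(0, 0))
})

test_that("the fit equals the closed-form normal-equations oracle", {
  set.seed(101)
  for (i in 1:20) {
    truth <- c(runif(1, 0, 5), runif(1, 0, 5))
    sp <- truth[1] * refs$curves[1, ] + truth[2] * refs$curves[2, ] +
      rnorm(length(refs$wavelength_nm), sd = 0.01)
    fit <- unmix_frame(sp, refs)
    oracle <- normal_equations_fit(refs, sp)
    expect_lt(max(abs(fit$coefficients - oracle)) / max(abs(oracle)), 1e-10)
  }
})

test_that("unconstrained unmixing is linear and scale equivariant", {
  set.seed(7)
  m <- length(refs$wavelength_nm)
  s1 <- runif(m); s2 <- runif(m)
  f <- function(s) unmix_frame(s, refs)$coefficients
  expect_equal(f(2.5 * s1 + 0.3 * s2), 2.5 * f(s1) + 0.3 * f(s2),
               tolerance = 1e-10)
  expect_equal(f(7 * s1), 7 * f(s1), tolerance = 1e-10)
})

test_that("reversing fluorophore order swaps coefficient rows exactly", {
  cfg <- test_config()
  s <- quietly(simulate_session(cfg))
  rev_refs <- reference_spectra(s$refs$curves[2:1, ], s$refs$wavelength_nm,
                                fluorophores = s$refs$fluorophores[2:1])
  u1 <- quietly(unmix_session(s$frames$region1, s$refs))
  u2 <- quietly(unmix_session(s$frames$region1, rev_refs))
  expect_equal(u1$coeff["gcamp", ], u2$coeff["gcamp", ], tolerance = 1e-12)
  expect_equal(u1$coeff["tdtomato", ], u2$coeff["tdtomato", ], tolerance = 1e-12)
  expect_identical(rownames(u2$coeff), c("tdtomato", "gcamp"))
})

test_that("grid mismatches and ill-conditioned references are rejected", {
  expect_error(unmix_frame(rep(1, 10), refs), "grid mismatch")
  s <- quietly(simulate_session(test_config()))
  bad <- s$frames$region1
  bad$wavelength_nm <- bad$wavelength_nm + 0.5
  expect_error(unmix_session(bad, refs), "grids must match")
  # two nearly identical curves: condition number explodes
  near <- refs$curves
  near[2, ] <- refs$curves[1, ] * (1 + 1e-9 * seq_len(ncol(near)))
  near[2, ] <- near[2, ] / max(near[2, ])
  bad_refs <- reference_spectra(near, refs$wavelength_nm)
  expect_error(unmix_frame(rep(1, ncol(near)), bad_refs), "unidentifiable")
})

test_that("noiseless sessions invert the forward model to numerical precision", {
  cfg <- test_config(noise_sd = 0, motion_amplitude = 0, bleach_tau_s = Inf,
                     red_noise_sd = 0)
  s <- quietly(simulate_session(cfg))
  u <- quietly(unmix_session(s$frames$region1, s$refs))
  err <- abs(u$coeff - s$truth$coeff_true$region1)
  expect_lt(max(err) / max(s$truth$coeff_true$region1), 1e-8)
})

test_that("nonnegative unmixing matches an enumeration oracle", {
  # For two fluorophores, the NNLS optimum is the best feasible candidate
  # among: the unconstrained fit, each single-curve fit clamped at zero,
  # and the origin. Enumerate and compare.
  X <- t(refs$curves)
  nnls_oracle <- function(y) {
    cand <- list(c(0, 0))
    b <- normal_equations_fit(refs, y)
    if (all(b >= 0)) cand <- c(cand, list(b))
    for (j in 1:2) {
      bj <- sum(X[, j] * y) / sum(X[, j]^2)
      v <- c(0, 0); v[j] <- max(bj, 0)
      cand <- c(cand, list(v))
    }
    obj <- vapply(cand, function(b) sum((y - X %*% b)^2), numeric(1))
    cand[[which.min(obj)]]
  }
  set.seed(33)
  for (i in 1:25) {
    # half the draws force a negative unconstrained coefficient
    y <- if (i %% 2 == 0) {
      0.5 * refs$curves[1, ] - 0.2 * refs$curves[2, ] + rnorm(ncol(X), sd = 0.05)
    } else {
      runif(1, 0, 3) * refs$curves[1, ] + runif(1, 0, 3) * refs$curves[2, ] +
        rnorm(ncol(X), sd = 0.05)
    }
    fit <- unmix_frame(y, refs, nonnegative = TRUE)$coefficients
    expect_true(all(fit >= 0))
    expect_equal(unname(fit), unname(nnls_oracle(y)), tolerance = 1e-8)
  }
})
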