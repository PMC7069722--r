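#' Simulation configuration
#'
#' Bundles every parameter of the synthetic dual-region spectral photometry
#' session. Defaults reproduce the recording conditions of the spectrometer
#' system the package models: 10 Hz spectral frames, 5-minute sessions,
#' band-limited (0.1-0.5 Hz) shared calcium dynamics, slow exponential
#' photobleaching and occasional multiplicative motion pulses common to both
#' fluorophores within a fiber.
#'
#' @param duration_s Session length in seconds.
#' @param frame_rate_hz Spectral acquisition rate (Hz). Must exceed twice the
#'   upper band edge so the band of interest is resolvable.
#' @param wavelength_nm Wavelength grid (nm) of the emulated spectrometer.
#' @param emission_peaks_nm Named peak emission wavelengths of the green
#'   (GCaMP6f) and red (tdTomato) fluorophores.
#' @param noise_sd Additive Gaussian noise per spectral sample (a.u.; the
#'   green coefficient has mean amplitude near `green_baseline`).
#' @param seed Integer RNG seed; identical configs and seeds give bit-identical
#'   sessions.
#' @param rho_band_target Target Pearson correlation of the two regions'
#'   band-limited latent calcium components, in \[-0.98, 0.98\].
#' @param band `(f_lo, f_hi)` Hz band the latent components occupy.
#' @param bleach_tau_s Photobleaching time constant (s); `Inf` disables it.
#' @param motion_amplitude Peak fractional amplitude of motion pulses
#'   (0.1 = 10% common-mode excursions).
#' @param n_motion_events Number of motion pulses per session.
#' @param transient_rise_s,transient_decay_s Rise/decay time constants (s) of
#'   the difference-of-exponentials calcium transient kernel.
#' @param transient_amplitude Peak dF/F-scale amplitude of exploration-locked
#'   transients (set 0 to disable).
#' @param n_bouts Number of exploration bouts to schedule (0 for none).
#' @param bout_duration_s Length-2 range (s) from which bout durations are drawn.
#' @param phase Task phase label for scheduled bouts.
#' @param p_novel Probability a bout is at the novel-location object.
#' @param ca_noise_sd Broadband (white) noise added to each region's calcium
#'   trace, in units of the unit-variance latent component.
#' @param green_baseline,green_gain Affine map from calcium activity to the
#'   green coefficient: `c_g = green_baseline + green_gain * ca`.
#' @param red_level,red_noise_sd Mean and relative noise of the
#'   activity-independent red (motion reference) coefficient.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(duration_s = 300,
                       frame_rate_hz = 10,
                       wavelength_nm = seq(500, 650, by = 2),
                       emission_peaks_nm = c(gcamp = 512, tdtomato = 581),
                       noise_sd = 0.01,
                       seed = 1L,
                       rho_band_target = 0.4,
                       band = c(0.1, 0.5),
                       bleach_tau_s = 300,
                       motion_amplitude = 0.1,
                       n_motion_events = 6,
                       transient_rise_s = 0.2,
                       transient_decay_s = 1.5,
                       transient_amplitude = 1,
                       n_bouts = 10,
                       bout_duration_s = c(1, 3),
                       phase = "encoding",
                       p_novel = 0.5,
                       ca_noise_sd = 0.05,
                       green_baseline = 1,
                       green_gain = 0.25,
                       red_level = 2,
                       red_noise_sd = 0.02) {
  cfg <- list(duration_s = duration_s, frame_rate_hz = frame_rate_hz,
              wavelength_nm = as.numeric(wavelength_nm),
              emission_peaks_nm = emission_peaks_nm,
              noise_sd = noise_sd, seed = as.integer(seed),
              rho_band_target = rho_band_target, band = band,
              bleach_tau_s = bleach_tau_s,
              motion_amplitude = motion_amplitude,
              n_motion_events = n_motion_events,
              transient_rise_s = transient_rise_s,
              transient_decay_s = transient_decay_s,
              transient_amplitude = transient_amplitude,
              n_bouts = n_bouts, bout_duration_s = bout_duration_s,
              phase = phase, p_novel = p_novel,
              ca_noise_sd = ca_noise_sd,
              green_baseline = green_baseline, green_gain = green_gain,
              red_level = red_level, red_noise_sd = red_noise_sd)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (frame_rate_hz <= 2 * band[2])
      stop("configuration error: frame_rate_hz must exceed 2 * band upper edge")
    n <- duration_s * frame_rate_hz
    if (abs(n - round(n)) > 1e-9)
      stop("configuration error: duration_s * frame_rate_hz must be an integer frame count")
    if (abs(rho_band_target) > 0.98)
      stop("configuration error: rho_band_target must lie in [-0.98, 0.98]")
    if (length(wavelength_nm) < 16 || any(diff(wavelength_nm) <= 0))
      stop("configuration error: wavelength grid must be strictly increasing with >= 16 bins")
    if (band[1] <= 0 || band[1] >= band[2])
      stop("configuration error: band must satisfy 0 < f_lo < f_hi")
    if (motion_amplitude < 0 || motion_amplitude >= 1)
      stop("configuration error: motion_amplitude must be in [0, 1)")
  })
  invisible(cfg)
}

n_frames <- function(cfg) as.integer(round(cfg$duration_s * cfg$frame_rate_hz))

#' Generate fluorophore reference emission spectra
#'
#' Builds the two "standard emission curves" the unmixing fits against:
#' unimodal, log-normal-shaped spectral densities peaking at the green and red
#' fluorophores' nominal emission maxima, max-normalized to 1 on the
#' configured wavelength grid.
#'
#' @param config A [sim_config()].
#' @param shape_sdlog Log-sd of the log-normal shape (spectral width).
#' @param onset_offset_nm Distance (nm) from the curve's onset to its peak.
#' @return A [reference_spectra()] object; attribute `condition_number`
#'   reports the conditioning of the implied unmixing design.
#' @export
generate_reference_spectra <- function(config, shape_sdlog = 0.35,
                                       onset_offset_nm = 40) {
  wl <- config$wavelength_nm
  peaks <- config$emission_peaks_nm
  if (length(unique(peaks)) < length(peaks))
    stop("configuration error: fluorophore emission peaks coincide; unmixing is unidentifiable")
  if (min(peaks) <= min(wl) || max(peaks) >= max(wl))
    stop("configuration error: wavelength grid too narrow to contain both emission peaks")
  # log-normal with mode at `onset_offset_nm` above the curve onset, so the
  # peak lands exactly at the nominal emission maximum
  meanlog <- log(onset_offset_nm) + shape_sdlog^2
  curves <- t(vapply(peaks, function(p) {
    d <- stats::dlnorm(wl - (p - onset_offset_nm), meanlog, shape_sdlog)
    d / max(d)
  }, numeric(length(wl))))
  reference_spectra(curves, wl, fluorophores = names(peaks))
}

# Exactly band-limited unit-variance noise: white noise passed through a
# zero-phase FFT brick-wall band-pass. Brick-wall (rather than IIR) filtering
# keeps the stopband exactly empty, so control bands see no leakage of the
# shared component.
bandlimited_noise <- function(n, fs, f_lo, f_hi) {
  zh <- stats::fft(stats::rnorm(n))
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)  # two-sided frequency magnitude
  zh[f < f_lo | f > f_hi] <- 0 + 0i
  x <- Re(stats::fft(zh, inverse = TRUE) / n)
  x / stats::sd(x)
}

#' Difference-of-exponentials calcium transient kernel
#'
#' `k(t) = exp(-t/decay) - exp(-t/rise)`, normalized to unit peak. With the
#' default 0.2 s rise and 1.5 s decay the kernel approximates GCaMP6f
#' response kinetics at the order-of-magnitude level.
#'
#' @param frame_rate_hz Sampling rate (Hz).
#' @param rise_s,decay_s Time constants (s).
#' @param length_s Kernel support (s); default covers ~5 decay constants.
#' @return Numeric vector sampled at the frame rate, peak value 1.
#' @export
transient_kernel <- function(frame_rate_hz = 10, rise_s = 0.2, decay_s = 1.5,
                             length_s = rise_s + 5 * decay_s) {
  t <- seq(0, length_s, by = 1 / frame_rate_hz)
  k <- exp(-t / decay_s) - exp(-t / rise_s)
  k / max(k)
}

#' Simulate a behavioral bout schedule
#'
#' Places non-overlapping exploration bouts inside the session with at least
#' `min_gap_s` between bouts (so +/-3 s peri-event windows never overlap) and
#' at least `margin_s` clearance from both session ends (so every bout
#' survives peri-event alignment).
#'
#' @param config A [sim_config()] supplying session length, bout count, bout
#'   duration range, phase and the novel-object probability.
#' @param min_gap_s Minimum inter-bout gap (s).
#' @param margin_s Minimum clearance from both recording edges (s).
#' @param novel_time_ratio Optional novel:old total exploration-time ratio.
#'   When given, bout labels alternate and per-class durations are set so the
#'   realized time ratio is exact (useful as behavioral ground truth).
#' @return An [event_table()].
#' @export
simulate_behavior_schedule <- function(config, min_gap_s = 6, margin_s = 3.5,
                                       novel_time_ratio = NULL) {
  n <- config$n_bouts
  if (n == 0) return(event_table(numeric(0), numeric(0), character(0), character(0)))
  if (is.null(novel_time_ratio)) {
    dur <- stats::runif(n, config$bout_duration_s[1], config$bout_duration_s[2])
    object <- ifelse(stats::runif(n) < config$p_novel, "novel", "old")
    if (n >= 2 && length(unique(object)) == 1)  # keep both objects represented
      object[sample.int(n, 1)] <- setdiff(c("novel", "old"), object[1])
  } else {
    stopifnot(novel_time_ratio > 0)
    n_nov <- ceiling(n / 2); n_old <- n - n_nov
    if (n_old == 0) stop("configuration error: need >= 2 bouts for a time ratio")
    object <- rep(c("novel", "old"), length.out = n)
    base <- mean(config$bout_duration_s)
    dur <- ifelse(object == "novel", base * novel_time_ratio * n_old / n_nov, base)
  }
  need <- 2 * margin_s + sum(dur) + (n - 1) * min_gap_s
  if (need > config$duration_s)
    stop(sprintf(
      "configuration error: cannot place %d bouts (need %.1f s, session is %.1f s)",
      n, need, config$duration_s))
  slack <- config$duration_s - need
  u <- stats::runif(n + 1); extra <- slack * u / sum(u)
  onset <- margin_s + cumsum(extra[seq_len(n)]) +
    c(0, cumsum(dur[-n] + min_gap_s))
  # snap to the frame grid so event and photometry clocks agree exactly
  onset <- round(onset * config$frame_rate_hz) / config$frame_rate_hz
  event_table(onset, onset + dur, object, config$phase)
}

#' Simulate two regions' latent calcium activity
#'
#' Each region's calcium trace is `w * shared + sqrt(1 - w^2) * independent`
#' (all components exactly band-limited to `config$band` and unit variance),
#' plus exploration-locked nonnegative transients and a small broadband noise
#' floor. The mixing weight `w = sqrt(|rho_band_target|)` makes the population
#' Pearson correlation of the two band-limited parts equal `rho_band_target`
#' (the shared part enters region 2 with a sign flip when the target is
#' negative).
#'
#' @param config A [sim_config()].
#' @return A list with `region1`, `region2` ([region_trace()]s) and `truth`,
#'   the session ground truth: the shared latent, each region's band-limited
#'   part, the injected transients (and their per-bout amplitudes) and the
#'   bout schedule.
#' @export
simulate_two_region_calcium <- function(config) {
  validate_sim_config(config)
  if (abs(config$rho_band_target) > 0.98)
    stop("configuration error: rho_band_target must lie in [-0.98, 0.98]")
  set.seed(config$seed)
  n <- n_frames(config); fs <- config$frame_rate_hz
  s  <- bandlimited_noise(n, fs, config$band[1], config$band[2])
  e1 <- bandlimited_noise(n, fs, config$band[1], config$band[2])
  e2 <- bandlimited_noise(n, fs, config$band[1], config$band[2])
  w <- sqrt(abs(config$rho_band_target))
  sgn <- if (config$rho_band_target < 0) -1 else 1
  L1 <- w * s + sqrt(1 - w^2) * e1
  L2 <- sgn * w * s + sqrt(1 - w^2) * e2

  schedule <- simulate_behavior_schedule(config)
  kern <- transient_kernel(fs, config$transient_rise_s, config$transient_decay_s)
  tr1 <- tr2 <- numeric(n)
  amps <- NULL
  if (nrow(schedule) > 0 && config$transient_amplitude > 0) {
    a1 <- config$transient_amplitude * stats::runif(nrow(schedule), 0.8, 1.2)
    a2 <- config$transient_amplitude * stats::runif(nrow(schedule), 0.8, 1.2)
    idx0 <- round(schedule$onset_s * fs) + 1
    for (b in seq_len(nrow(schedule))) {
      j <- idx0[b]:min(n, idx0[b] + length(kern) - 1)
      tr1[j] <- tr1[j] + a1[b] * kern[seq_along(j)]
      tr2[j] <- tr2[j] + a2[b] * kern[seq_along(j)]
    }
    amps <- cbind(region1 = a1, region2 = a2)
  }
  ca1 <- L1 + tr1 + config$ca_noise_sd * stats::rnorm(n)
  ca2 <- L2 + tr2 + config$ca_noise_sd * stats::rnorm(n)

  truth <- list(latent_shared = s,
                band_parts = cbind(region1 = L1, region2 = L2),
                transients = cbind(region1 = tr1, region2 = tr2),
                transient_amplitudes = amps,
                rho_band_target = config$rho_band_target,
                event_schedule = schedule,
                seed = config$seed)
  list(region1 = region_trace(ca1, fs, "raw"),
       region2 = region_trace(ca2, fs, "raw"),
       truth = truth)
}

#' Render spectral frames from latent calcium activity
#'
#' Forward model of the spectrometer acquisition. Per fiber and frame,
#' `frame(t, l) = motion(t) * bleach(t) * (c_g(t) ref_g(l) + c_r(t) ref_r(l))
#' + noise`, where the green coefficient is affine in the region's calcium
#' trace and the red coefficient is activity-independent (constant plus
#' noise). Motion pulses and bleaching multiply both fluorophores equally
#' (common mode), which is what makes ratiometric correction work downstream.
#' Negative post-noise intensities are clipped to zero and counted; a clip
#' fraction above 1% triggers a warning.
#'
#' @param calcium Output of [simulate_two_region_calcium()] (or a compatible
#'   list with `region1`, `region2`, `truth`).
#' @param refs A [reference_spectra()] on the config's grid.
#' @param config The [sim_config()] used to generate `calcium`.
#' @return A list with `fibers` (a named list of two [spectrum_frames()]) and
#'   `truth`: the input ground truth extended with the per-fiber coefficients
#'   as rendered (`coeff_true`, rows gcamp/tdtomato, including the
#'   motion-and-bleach gain — what a perfect unmixing recovers), the
#'   artifact-free coefficients (`coeff_clean` — what a perfect
#'   motion/bleach correction recovers), the motion and bleach traces, and
#'   per-fiber clip fractions.
#' @export
render_spectral_frames <- function(calcium, refs, config) {
  n <- n_frames(config); fs <- config$frame_rate_hz
  stopifnot(length(calcium$region1$values) == n)
  if (max(abs(refs$wavelength_nm - config$wavelength_nm)) > 0)
    stop("render_spectral_frames: reference grid differs from config grid")
  # separate stream from the latent draw so render is reproducible standalone
  set.seed((config$seed + 99991L) %% .Machine$integer.max)
  t <- (0:(n - 1)) / fs
  bleach <- if (is.finite(config$bleach_tau_s)) exp(-t / config$bleach_tau_s) else rep(1, n)
  motion <- rep(1, n)
  if (config$n_motion_events > 0 && config$motion_amplitude > 0) {
    centers <- stats::runif(config$n_motion_events, 0.05, 0.95) * config$duration_s
    signs <- sample(c(-1, 1), config$n_motion_events, replace = TRUE)
    for (i in seq_len(config$n_motion_events))
      motion <- motion + signs[i] * config$motion_amplitude *
        exp(-((t - centers[i])^2) / (2 * 0.5^2))
  }
  if (any(motion <= 0)) stop("motion trace is not strictly positive; lower motion_amplitude")

  ref_g <- refs$curves[1, ]; ref_r <- refs$curves[2, ]
  fibers <- list(); coeff_true <- list(); coeff_clean <- list(); clip <- c()
  for (rg in c("region1", "region2")) {
    ca <- calcium[[rg]]$values
    c_g <- pmax(config$green_baseline + config$green_gain * ca, 0)
    c_r <- pmax(config$red_level * (1 + config$red_noise_sd * stats::rnorm(n)), 1e-6)
    gain <- motion * bleach
    inten <- (gain * c_g) %o% ref_g + (gain * c_r) %o% ref_r
    if (config$noise_sd > 0)
      inten <- inten + matrix(stats::rnorm(length(inten), sd = config$noise_sd),
                              nrow = n)
    neg <- inten < 0
    clip[rg] <- mean(neg)
    inten[neg] <- 0
    if (clip[rg] > 0.01)
      warning(sprintf("render_spectral_frames: %.2f%% of samples clipped at zero in %s",
                      100 * clip[rg], rg))
    fibers[[rg]] <- spectrum_frames(inten, config$wavelength_nm, fs)
    coeff_true[[rg]] <- rbind(gcamp = gain * c_g, tdtomato = gain * c_r)
    coeff_clean[[rg]] <- rbind(gcamp = c_g, tdtomato = c_r)
  }
  truth <- calcium$truth
  truth$coeff_true <- coeff_true
  truth$coeff_clean <- coeff_clean
  truth$motion_trace <- motion
  truth$bleach_trace <- bleach
  truth$bleach_tau_s <- config$bleach_tau_s
  truth$clip_fraction <- clip
  list(fibers = fibers, truth = truth)
}

#' Simulate a complete dual-fiber spectral photometry session
#'
#' Convenience wrapper chaining [generate_reference_spectra()],
#' [simulate_two_region_calcium()] and [render_spectral_frames()].
#'
#' @param config A [sim_config()].
#' @return A list: `config`, `refs`, `frames` (two [spectrum_frames()]),
#'   `calcium` (the two latent [region_trace()]s), `events` and `truth`.
#' @export
simulate_session <- function(config = sim_config()) {
  refs <- generate_reference_spectra(config)
  ca <- simulate_two_region_calcium(config)
  rend <- render_spectral_frames(ca, refs, config)
  list(config = config, refs = refs, frames = rend$fibers,
       calcium = list(region1 = ca$region1, region2 = ca$region2),
       events = rend$truth$event_schedule,
       truth = rend$truth)
}
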