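#' Default frequency bands
#'
#' The standard segmentation of the 0.05-2 Hz range used throughout the
#' package: the band of interest for inter-regional calcium correlation is
#' 0.1-0.5 Hz; 1-2 Hz serves as a control band.
#'
#' @return A 4 x 2 matrix of `(f_lo, f_hi)` rows in Hz.
#' @export
default_bands <- function() {
  b <- rbind(c(0.05, 0.1), c(0.1, 0.5), c(0.5, 1), c(1, 2))
  dimnames(b) <- list(c("0.05-0.1", "0.1-0.5", "0.5-1", "1-2"),
                      c("f_lo_hz", "f_hi_hz"))
  b
}

#' Morlet continuous wavelet transform
#'
#' FFT-based CWT with an analytic Morlet mother (center frequency `omega0`),
#' Torrence-Compo normalization (each row has unit response energy so white
#' noise gives flat expected power across scales). The input is mean-removed
#' and zero-padded to the next power of two before transforming.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param scales Wavelet scales (s).
#' @param omega0 Morlet center-frequency parameter (default 6, the standard
#'   choice for which scale and Fourier period nearly coincide).
#' @return A complex `length(scales) x length(x)` matrix of coefficients.
#' @export
morlet_cwt <- function(x, fs, scales, omega0 = 6) {
  n <- length(x)
  n2 <- 2^ceiling(log2(n)) * 2
  xh <- stats::fft(c(x - mean(x), rep(0, n2 - n)))
  k <- 0:(n2 - 1)
  omega <- ifelse(k <= n2 / 2, k, k - n2) * 2 * pi * fs / n2
  W <- matrix(0 + 0i, length(scales), n)
  for (j in seq_along(scales)) {
    s <- scales[j]
    psi <- sqrt(2 * pi * s * fs) * pi^-0.25 *
      exp(-((s * omega - omega0)^2) / 2) * (omega > 0)
    W[j, ] <- stats::fft(xh * psi, inverse = TRUE)[1:n] / n2
  }
  W
}

# Fourier factor: wavelength of the Fourier period corresponding to scale 1
morlet_fourier_factor <- function(omega0 = 6) 4 * pi / (omega0 + sqrt(2 + omega0^2))

#' Decompose a trace into frequency-band components
#'
#' Continuous Morlet wavelet transform on a log-spaced scale grid covering
#' the requested bands (default 0.05-2 Hz, 12 voices per octave), followed by
#' band-wise real reconstruction: each band component is the inverse-CWT
#' partial sum over the scales whose center frequencies fall inside the band.
#' Frames inside the cone of influence (within the e-folding radius
#' `sqrt(2) * s` of either edge, evaluated at the band's largest scale) are
#' flagged invalid and excluded from downstream correlation.
#'
#' @param trace A [region_trace()] (typically at stage `"dff"`).
#' @param bands Matrix of `(f_lo, f_hi)` rows in Hz; see [default_bands()].
#' @param omega0 Morlet center-frequency parameter.
#' @param n_voices Voices (scales) per octave.
#' @param mode `"reconstruction"` (real band-limited signal, default) or
#'   `"envelope"` (scale-summed wavelet magnitude, a power-envelope variant).
#' @return An object of class `band_decomposition`: `bands`, `components`
#'   (band x frame), `coi_valid` (logical band x frame), `time_s`,
#'   `frame_rate_hz` and `params` (wavelet metadata, including scales and
#'   center frequencies).
#' @export
morlet_decompose <- function(trace, bands = default_bands(), omega0 = 6,
                             n_voices = 12,
                             mode = c("reconstruction", "envelope")) {
  mode <- match.arg(mode)
  bands <- matrix(as.numeric(bands), ncol = 2,
                  dimnames = dimnames(bands))
  fs <- trace$frame_rate_hz
  x <- trace$values
  n <- length(x)
  if (any(bands[, 1] <= 0) || any(bands[, 2] <= bands[, 1]))
    stop("configuration error: bands must satisfy 0 < f_lo < f_hi")
  if (any(bands[, 2] > fs / 2))
    stop("configuration error: band upper edge exceeds the Nyquist frequency")
  f_min <- min(bands); f_max <- max(bands)
  if (n / fs < 3 / f_min)
    stop(sprintf("morlet_decompose: trace too short; need >= %.0f s (3 periods of %g Hz)",
                 3 / f_min, f_min))
  ff <- morlet_fourier_factor(omega0)
  s0 <- 1 / (ff * f_max)
  J <- ceiling(n_voices * log2(f_max / f_min))
  scales <- s0 * 2^((0:J) / n_voices)
  cf <- 1 / (ff * scales)
  W <- morlet_cwt(x, fs, scales, omega0)
  # Torrence-Compo reconstruction constant for omega0 = 6
  recon_const <- (1 / n_voices) * sqrt(1 / fs) / (0.776 * pi^-0.25)
  nb <- nrow(bands)
  comps <- matrix(0, nb, n)
  valid <- matrix(TRUE, nb, n)
  t_rel <- (0:(n - 1)) / fs
  for (b in seq_len(nb)) {
    hi_inclusive <- bands[b, 2] >= f_max
    idx <- which(cf >= bands[b, 1] &
                   (if (hi_inclusive) cf <= bands[b, 2] else cf < bands[b, 2]))
    if (!length(idx))
      stop(sprintf("morlet_decompose: no scales fall in band %g-%g Hz; increase n_voices",
                   bands[b, 1], bands[b, 2]))
    wgt <- 1 / sqrt(scales[idx])
    comps[b, ] <- recon_const * (
      if (mode == "reconstruction") colSums(Re(W[idx, , drop = FALSE]) * wgt)
      else colSums(Mod(W[idx, , drop = FALSE]) * wgt))
    coi_s <- sqrt(2) * max(scales[idx])
    valid[b, ] <- t_rel >= coi_s & t_rel <= (t_rel[n] - coi_s)
  }
  rownames(comps) <- rownames(valid) <- rownames(bands)
  structure(
    list(bands = bands, components = comps, coi_valid = valid,
         time_s = trace$time_s, frame_rate_hz = fs,
         params = list(omega0 = omega0, n_voices = n_voices, mode = mode,
                       scales = scales, center_freq_hz = cf,
                       recon_const = recon_const)),
    class = "band_decomposition")
}

#' @export
print.band_decomposition <- function(x, ...) {
  cat(sprintf("<band_decomposition> %d bands x %d frames @ %g Hz (Morlet omega0=%g, %d voices/octave, mode '%s')\n",
              nrow(x$bands), ncol(x$components), x$frame_rate_hz,
              x$params$omega0, x$params$n_voices, x$params$mode))
  for (b in seq_len(nrow(x$bands)))
    cat(sprintf("  %g-%g Hz: sd %.4g, %d/%d frames outside cone of influence\n",
                x$bands[b, 1], x$bands[b, 2], stats::sd(x$components[b, ]),
                sum(x$coi_valid[b, ]), ncol(x$components)))
  invisible(x)
}

#' Zero-phase Butterworth band-pass component
#'
#' Alternative band-extraction backend used to cross-check the wavelet
#' reconstruction: a forward-backward Butterworth band-pass of the trace.
#'
#' @param trace A [region_trace()].
#' @param band `(f_lo, f_hi)` in Hz.
#' @param order Single-pass Butterworth order.
#' @return Numeric band-limited signal, same length as the input.
#' @export
butter_band_component <- function(trace, band, order = 2) {
  fs <- trace$frame_rate_hz
  if (band[2] > fs / 2) stop("configuration error: band exceeds Nyquist")
  bp <- signal::butter(order, band / (fs / 2), type = "pass")
  filtfilt_padded(bp, trace$values - mean(trace$values),
                  padlen = round(3 * fs / band[1]))
}
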