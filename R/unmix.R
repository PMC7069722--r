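#' Unmix a single emission spectrum
#'
#' Least-squares fit of one measured spectrum to the reference emission
#' curves: finds the coefficients minimizing
#' `|| spectrum - sum_k coeff_k * ref_k ||^2` over the wavelength grid.
#' With `nonnegative = TRUE` the fit is constrained to `coeff >= 0`
#' (Lawson-Hanson active set), which guards low-SNR frames against sign flips.
#'
#' @param spectrum Numeric intensity vector on the reference grid.
#' @param refs A [reference_spectra()].
#' @param nonnegative Constrain coefficients to be nonnegative?
#' @param cond_max Condition-number threshold above which the design is
#'   declared unidentifiable.
#' @return A list with `coefficients` (named per fluorophore) and
#'   `residual_rms` (root-mean-square fit residual).
#' @export
unmix_frame <- function(spectrum, refs, nonnegative = FALSE, cond_max = 1e6) {
  X <- t(refs$curves)  # wavelengths x fluorophores
  if (length(spectrum) != nrow(X))
    stop(sprintf("unmix_frame: spectrum has %d bins but references have %d (grid mismatch)",
                 length(spectrum), nrow(X)))
  if (nrow(X) < ncol(X) + 2)
    stop("unmix_frame: need at least 2 more wavelength bins than fluorophores")
  cn <- kappa(X, exact = TRUE)
  if (cn > cond_max)
    stop(sprintf("unmix_frame: reference curves unidentifiable (condition number %.3g > %.3g)",
                 cn, cond_max))
  co <- if (nonnegative) nnls_solve(X, spectrum) else qr.coef(qr(X), spectrum)
  names(co) <- refs$fluorophores
  res <- spectrum - X %*% co
  list(coefficients = co, residual_rms = sqrt(mean(res^2)))
}

#' Unmix a spectral frame series
#'
#' Frame-wise application of [unmix_frame()] to a whole session, returning
#' per-fluorophore coefficient time series (the raw fluorescence signals F),
#' per-frame residual RMS and the session-level condition number. The 99th
#' percentile of the residual RMS is reported via `message()` as a fit-quality
#' summary.
#'
#' @param frames A [spectrum_frames()] series.
#' @param refs A [reference_spectra()] on the identical wavelength grid.
#' @param nonnegative Constrain all coefficients to be nonnegative?
#' @param cond_max Condition-number threshold for unidentifiability.
#' @return An object of class `unmixed_traces`: `time_s`, `coeff`
#'   (fluorophore x frame matrix), `residual_rms`, `condition_number`,
#'   `frame_rate_hz`, `fluorophores`.
#' @export
unmix_session <- function(frames, refs, nonnegative = FALSE, cond_max = 1e6) {
  if (length(frames$wavelength_nm) != length(refs$wavelength_nm) ||
      max(abs(frames$wavelength_nm - refs$wavelength_nm)) > 0)
    stop("unmix_session: frame and reference wavelength grids must match exactly")
  dt <- diff(frames$time_s)
  if (length(dt) && (max(dt) - min(dt)) > 1e-6)
    stop("unmix_session: frame clock is not uniform (missing frames?)")
  X <- t(refs$curves)
  cn <- kappa(X, exact = TRUE)
  if (cn > cond_max)
    stop(sprintf("unmix_session: reference curves unidentifiable (condition number %.3g > %.3g)",
                 cn, cond_max))
  Y <- t(frames$intensity)  # wavelengths x frames
  if (nonnegative) {
    coef <- apply(Y, 2, function(y) nnls_solve(X, y))
  } else {
    coef <- qr.coef(qr(X), Y)
  }
  coef <- matrix(coef, nrow = ncol(X),
                 dimnames = list(refs$fluorophores, NULL))
  if (any(!is.finite(coef))) {
    bad <- which(!apply(is.finite(coef), 2, all))[1]
    stop(sprintf("unmix_session: fit failed at frame %d", bad))
  }
  res <- Y - X %*% coef
  rrms <- sqrt(colMeans(res^2))
  message(sprintf(
    "unmix_session: %d frames, condition number %.3g, residual RMS p99 = %.4g",
    ncol(coef), cn, stats::quantile(rrms, 0.99)))
  structure(
    list(time_s = frames$time_s, coeff = coef, residual_rms = rrms,
         condition_number = cn, frame_rate_hz = frames$frame_rate_hz,
         fluorophores = refs$fluorophores),
    class = "unmixed_traces")
}

#' @export
print.unmixed_traces <- function(x, ...) {
  cat(sprintf("<unmixed_traces> %d frames @ %g Hz; condition number %.3g\n",
              ncol(x$coeff), x$frame_rate_hz, x$condition_number))
  for (f in x$fluorophores)
    cat(sprintf("  %-9s mean %.4g, sd %.4g\n", f,
                mean(x$coeff[f, ]), stats::sd(x$coeff[f, ])))
  invisible(x)
}

#' Extract one fluorophore's coefficient series as a region trace
#'
#' @param unmixed An `unmixed_traces` object.
#' @param fluorophore Row name to extract.
#' @return A [region_trace()] at stage `"raw"`.
#' @export
coeff_trace <- function(unmixed, fluorophore) {
  stopifnot(fluorophore %in% unmixed$fluorophores)
  region_trace(unmixed$coeff[fluorophore, ], unmixed$frame_rate_hz, "raw",
               t0 = unmixed$time_s[1])
}

# Lawson-Hanson nonnegative least squares; p is tiny (2-3 basis curves), so a
# plain active-set loop is ample.
nnls_solve <- function(X, y, tol = 1e-10, max_iter = 200) {
  p <- ncol(X)
  passive <- rep(FALSE, p)
  x <- numeric(p)
  w <- crossprod(X, y - X %*% x)
  iter <- 0
  while (any(!passive & w > tol) && iter < max_iter) {
    iter <- iter + 1
    passive[which.max(ifelse(passive, -Inf, w))] <- TRUE
    repeat {
      s <- numeric(p)
      s[passive] <- qr.coef(qr(X[, passive, drop = FALSE]), y)
      if (all(s[passive] > tol)) { x <- s; break }
      neg <- passive & s <= tol
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
    w <- crossprod(X, y - X %*% x)
  }
  as.numeric(x)
}
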