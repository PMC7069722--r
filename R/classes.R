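#' Construct a region trace
#'
#' A `region_trace` is one region's scalar time series on a uniform frame
#' clock: the raw fluorophore coefficient, a motion-corrected or high-passed
#' fluorescence signal, or the final dF/F. The `stage_label` records how far
#' along the processing chain the trace is; processing functions check it and
#' note (without failing) when a stage is skipped or reordered.
#'
#' @param values Numeric vector, one value per frame (a.u. for fluorescence,
#'   dimensionless for dF/F).
#' @param frame_rate_hz Sampling rate in Hz (default 10, the spectrometer
#'   acquisition rate).
#' @param stage_label One of `"raw"`, `"motion_corrected"`, `"highpassed"`,
#'   `"dff"`.
#' @param t0 Time of the first frame in seconds.
#' @return An object of class `region_trace` with fields `time_s`, `values`,
#'   `frame_rate_hz`, `stage_label`.
#' @export
region_trace <- function(values, frame_rate_hz = 10, stage_label = "raw", t0 = 0) {
  stopifnot(is.numeric(values), length(values) >= 1,
            is.numeric(frame_rate_hz), frame_rate_hz > 0)
  if (!all(is.finite(values))) stop("region_trace: values must be finite")
  stage_label <- match.arg(stage_label,
                           c("raw", "motion_corrected", "highpassed", "dff"))
  structure(
    list(time_s = t0 + (seq_along(values) - 1) / frame_rate_hz,
         values = as.numeric(values),
         frame_rate_hz = frame_rate_hz,
         stage_label = stage_label),
    class = "region_trace")
}

#' @export
print.region_trace <- function(x, ...) {
  cat(sprintf("<region_trace> %d frames @ %g Hz (%.1f s), stage '%s'\n",
              length(x$values), x$frame_rate_hz,
              length(x$values) / x$frame_rate_hz, x$stage_label))
  cat(sprintf("  values: mean %.4g, sd %.4g, range [%.4g, %.4g]\n",
              mean(x$values), stats::sd(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

# Internal: assert two traces share the frame clock.
check_same_clock <- function(a, b, what = "traces") {
  if (length(a$values) != length(b$values))
    stop(sprintf("%s differ in length (%d vs %d)", what,
                 length(a$values), length(b$values)))
  if (abs(a$frame_rate_hz - b$frame_rate_hz) > 1e-9)
    stop(sprintf("%s differ in frame rate", what))
  if (max(abs(a$time_s - b$time_s)) > 1e-6)
    stop(sprintf("%s are not on the same clock", what))
  invisible(TRUE)
}

# Internal: note (not fail) when an input arrives at an unexpected stage.
note_stage <- function(trace, expected, fun) {
  if (!identical(trace$stage_label, expected))
    message(sprintf("%s: input stage is '%s' (canonical order expects '%s'); proceeding",
                    fun, trace$stage_label, expected))
  invisible(TRUE)
}

#' Construct a spectral frame series
#'
#' Time-ordered per-frame emission spectra from one fiber: an
#' `n_frames x n_wavelengths` intensity matrix on a uniform 10 Hz (default)
#' frame clock with a shared wavelength grid.
#'
#' @param intensity Numeric matrix, frames in rows, wavelength bins in columns.
#' @param wavelength_nm Strictly increasing wavelength grid (nm), one entry per
#'   column of `intensity`.
#' @param frame_rate_hz Acquisition rate in Hz.
#' @param t0 Time of the first frame in seconds.
#' @return An object of class `spectrum_frames`.
#' @export
spectrum_frames <- function(intensity, wavelength_nm, frame_rate_hz = 10, t0 = 0) {
  intensity <- as.matrix(intensity)
  stopifnot(ncol(intensity) == length(wavelength_nm))
  if (!all(is.finite(intensity))) stop("spectrum_frames: intensity must be finite")
  if (any(diff(wavelength_nm) <= 0))
    stop("spectrum_frames: wavelength grid must be strictly increasing")
  structure(
    list(time_s = t0 + (seq_len(nrow(intensity)) - 1) / frame_rate_hz,
         wavelength_nm = as.numeric(wavelength_nm),
         intensity = intensity,
         frame_rate_hz = frame_rate_hz),
    class = "spectrum_frames")
}

#' @export
print.spectrum_frames <- function(x, ...) {
  cat(sprintf("<spectrum_frames> %d frames @ %g Hz, %d wavelength bins (%g-%g nm)\n",
              nrow(x$intensity), x$frame_rate_hz, length(x$wavelength_nm),
              min(x$wavelength_nm), max(x$wavelength_nm)))
  invisible(x)
}

#' Construct a reference spectra object
#'
#' Max-normalized emission curves for the fluorophores to be unmixed, on the
#' same wavelength grid as the frames they will be fitted against.
#'
#' @param curves Numeric matrix, one fluorophore per row, one wavelength bin
#'   per column. Each row is max-normalized to 1.
#' @param wavelength_nm Wavelength grid (nm).
#' @param fluorophores Character vector of row labels.
#' @return An object of class `reference_spectra`. The attribute
#'   `condition_number` carries the condition number of the curve matrix (the
#'   design whose Gram matrix the unmixing inverts).
#' @export
reference_spectra <- function(curves, wavelength_nm,
                              fluorophores = c("gcamp", "tdtomato")) {
  curves <- as.matrix(curves)
  stopifnot(nrow(curves) == length(fluorophores),
            ncol(curves) == length(wavelength_nm))
  if (any(curves < 0)) stop("reference_spectra: curves must be nonnegative")
  if (any(abs(apply(curves, 1, max) - 1) > 1e-8))
    stop("reference_spectra: each curve must be max-normalized to 1")
  rownames(curves) <- fluorophores
  obj <- structure(
    list(wavelength_nm = as.numeric(wavelength_nm),
         curves = curves,
         fluorophores = fluorophores),
    class = "reference_spectra")
  attr(obj, "condition_number") <- kappa(t(curves), exact = TRUE)
  obj
}

#' @export
print.reference_spectra <- function(x, ...) {
  pk <- x$wavelength_nm[apply(x$curves, 1, which.max)]
  cat(sprintf("<reference_spectra> %s on %d bins (%g-%g nm); peaks at %s nm; cond %.3g\n",
              paste(x$fluorophores, collapse = ", "),
              length(x$wavelength_nm), min(x$wavelength_nm), max(x$wavelength_nm),
              paste(pk, collapse = ", "), attr(x, "condition_number")))
  invisible(x)
}

#' Construct a behavioral event table
#'
#' Exploration bouts on the photometry clock, each labeled by object identity
#' (novel vs old location) and task phase (encoding vs retrieval). Bouts must
#' be sorted and non-overlapping.
#'
#' @param onset_s,offset_s Bout onset/offset times in seconds.
#' @param object Character, `"novel"` or `"old"` per bout.
#' @param phase Character, `"encoding"` or `"retrieval"` per bout (recycled).
#' @return A `data.frame` of class `event_table`.
#' @export
event_table <- function(onset_s, offset_s, object, phase = "encoding") {
  n <- length(onset_s)
  stopifnot(length(offset_s) == n, length(object) == n)
  phase <- rep_len(phase, n)
  if (n > 0) {
    if (any(offset_s <= onset_s)) stop("event_table: each onset must precede its offset")
    if (is.unsorted(onset_s, strictly = FALSE)) stop("event_table: rows must be sorted by onset")
    if (n > 1 && any(onset_s[-1] < offset_s[-n])) stop("event_table: bouts must not overlap")
    if (!all(object %in% c("novel", "old"))) stop("event_table: object must be 'novel' or 'old'")
    if (!all(phase %in% c("encoding", "retrieval")))
      stop("event_table: phase must be 'encoding' or 'retrieval'")
  }
  structure(
    data.frame(onset_s = as.numeric(onset_s), offset_s = as.numeric(offset_s),
               object = as.character(object), phase = as.character(phase),
               stringsAsFactors = FALSE),
    class = c("event_table", "data.frame"))
}
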