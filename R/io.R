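#' Write / read spectral frames as CSV
#'
#' Frames are stored with a `time_s` column followed by one column per
#' wavelength bin named `nm<wavelength>`; the frame rate and grid are also
#' written to a JSON sidecar (`<path>.json`).
#'
#' @param frames A [spectrum_frames()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_frames_csv <- function(frames, path) {
  df <- data.frame(time_s = frames$time_s, frames$intensity)
  names(df) <- c("time_s", paste0("nm", frames$wavelength_nm))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(wavelength_nm = frames$wavelength_nm,
         frame_rate_hz = frames$frame_rate_hz),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_frames_csv
#' @export
read_frames_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  wl <- as.numeric(sub("^nm", "", names(df)[-1]))
  sidecar <- paste0(path, ".json")
  fs <- if (file.exists(sidecar)) {
    jsonlite::read_json(sidecar)$frame_rate_hz
  } else {
    1 / stats::median(diff(df$time_s))
  }
  spectrum_frames(as.matrix(df[, -1]), wl, frame_rate_hz = fs, t0 = df$time_s[1])
}

#' Write / read a region trace as CSV
#'
#' Columns `time_s`, `value`; stage label and frame rate go to a JSON sidecar.
#'
#' @param trace A [region_trace()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace$time_s, value = trace$values),
                   path, row.names = FALSE)
  jsonlite::write_json(
    list(frame_rate_hz = trace$frame_rate_hz, stage_label = trace$stage_label),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else
    list(frame_rate_hz = 1 / stats::median(diff(df$time_s)), stage_label = "raw")
  region_trace(df$value, meta$frame_rate_hz, meta$stage_label, t0 = df$time_s[1])
}

#' Write / read a behavioral event table as CSV
#'
#' @param events An [event_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  event_table(df$onset_s, df$offset_s, df$object, df$phase)
}

#' Write unmixed coefficient traces as CSV
#'
#' Columns `time_s`, one per fluorophore coefficient, and `residual_rms`.
#'
#' @param unmixed An `unmixed_traces` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_unmixed_csv <- function(unmixed, path) {
  df <- data.frame(time_s = unmixed$time_s, t(unmixed$coeff),
                   residual_rms = unmixed$residual_rms)
  names(df) <- c("time_s", paste0("coeff_", unmixed$fluorophores), "residual_rms")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
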