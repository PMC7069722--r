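#' Align dF/F to behavioral bout onsets
#'
#' Extracts one fixed-length window of the trace per exploration bout, with
#' the bout onset defined as 0 s. Onsets are snapped to the nearest photometry
#' frame (the behavioral clock is assumed pre-synchronized; the maximum snap
#' error, at most half a frame interval, is reported). Bouts whose window
#' would cross either recording edge are dropped and counted.
#'
#' @param trace A [region_trace()], typically at stage `"dff"`.
#' @param events An [event_table()].
#' @param window `(lo, hi)` window in seconds relative to onset; frames with
#'   relative time in `[lo, hi)` are taken, so the default (-3, 3) window at
#'   10 Hz yields 60 samples per trial.
#' @return An object of class `aligned_trials`: `trials` (trial x time
#'   matrix), `time_rel_s`, `window_s`, `events` (the rows actually used),
#'   `n_dropped`, `frame_rate_hz`.
#' @export
align_trials <- function(trace, events, window = c(-3, 3)) {
  fs <- trace$frame_rate_hz
  n <- length(trace$values)
  n_w <- round((window[2] - window[1]) * fs)
  rel_idx <- round(window[1] * fs) + 0:(n_w - 1)
  time_rel <- rel_idx / fs
  if (nrow(events) == 0) {
    warning("align_trials: empty event table; returning no trials")
    return(structure(list(trials = matrix(numeric(0), 0, n_w),
                          time_rel_s = time_rel, window_s = window,
                          events = events, n_dropped = 0L,
                          frame_rate_hz = fs),
                     class = "aligned_trials"))
  }
  if (is.unsorted(events$onset_s) ||
      (nrow(events) > 1 && any(events$onset_s[-1] < events$offset_s[-nrow(events)])))
    stop("align_trials: events must be sorted and non-overlapping")
  onset_idx <- round((events$onset_s - trace$time_s[1]) * fs) + 1
  snap_err <- abs(events$onset_s - trace$time_s[pmin(pmax(onset_idx, 1), n)])
  message(sprintf("align_trials: max onset-to-frame snap error %.1f ms",
                  1000 * max(snap_err)))
  usable <- onset_idx + rel_idx[1] >= 1 & onset_idx + rel_idx[n_w] <= n
  n_dropped <- sum(!usable)
  if (n_dropped > 0)
    message(sprintf("align_trials: %d trial(s) dropped at the recording edges", n_dropped))
  kept <- which(usable)
  trials <- t(vapply(kept, function(i) trace$values[onset_idx[i] + rel_idx],
                     numeric(n_w)))
  structure(list(trials = trials, time_rel_s = time_rel, window_s = window,
                 events = events[kept, , drop = FALSE],
                 n_dropped = as.integer(n_dropped), frame_rate_hz = fs),
            class = "aligned_trials")
}

#' @export
print.aligned_trials <- function(x, ...) {
  cat(sprintf("<aligned_trials> %d trials x %d frames, window [%g, %g) s, %d dropped\n",
              nrow(x$trials), ncol(x$trials), x$window_s[1], x$window_s[2],
              x$n_dropped))
  invisible(x)
}

#' Default peri-event sub-windows
#'
#' Pre-exploring (-3 to -1 s), exploring (-1 to 1 s) and post-exploring
#' (1 to 3 s): three half-open 2 s sub-windows that exactly partition the
#' (-3, 3) s peri-event window.
#'
#' @return A data.frame with columns `subwindow`, `lo_s`, `hi_s`.
#' @export
default_subwindows <- function() {
  data.frame(subwindow = c("pre", "exploring", "post"),
             lo_s = c(-3, -1, 1), hi_s = c(-1, 1, 3),
             stringsAsFactors = FALSE)
}

#' Windowed cumulative activity
#'
#' Per trial and sub-window, the time-integral of dF/F (left-Riemann sum
#' times the frame interval), in units of dF/F x seconds: the "cumulative
#' activity" response-magnitude statistic. Sub-windows are half-open
#' `[lo, hi)`, so the three default windows partition the trial exactly and
#' their values add up to the whole-window integral.
#'
#' @param trials An [align_trials()] result.
#' @param subwindows Data.frame of sub-windows; see [default_subwindows()].
#' @return A `data.frame` (class `cumulative_activity`) with columns `trial`,
#'   `object`, `phase`, `subwindow`, `value`; the attribute `summary` holds
#'   mean and SEM per sub-window.
#' @export
cumulative_activity <- function(trials, subwindows = default_subwindows()) {
  dt <- 1 / trials$frame_rate_hz
  rel <- trials$time_rel_s
  for (w in seq_len(nrow(subwindows))) {
    nsamp <- sum(rel >= subwindows$lo_s[w] & rel < subwindows$hi_s[w])
    if (nsamp < 10)
      stop(sprintf("cumulative_activity: sub-window '%s' has %d samples; need >= 10",
                   subwindows$subwindow[w], nsamp))
  }
  nt <- nrow(trials$trials)
  out <- do.call(rbind, lapply(seq_len(nrow(subwindows)), function(w) {
    sel <- rel >= subwindows$lo_s[w] & rel < subwindows$hi_s[w]
    vals <- if (nt > 0) rowSums(trials$trials[, sel, drop = FALSE]) * dt else numeric(0)
    data.frame(trial = seq_len(nt),
               object = if (nt > 0) trials$events$object else character(0),
               phase = if (nt > 0) trials$events$phase else character(0),
               subwindow = subwindows$subwindow[w], value = vals,
               stringsAsFactors = FALSE)
  }))
  smry <- do.call(rbind, lapply(split(out$value, out$subwindow), function(v)
    data.frame(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)))))
  smry <- smry[subwindows$subwindow, , drop = FALSE]
  structure(out, summary = smry,
            class = c("cumulative_activity", "data.frame"))
}

#' Mean of the top-k dF/F peaks in an epoch
#'
#' Finds local maxima (strictly greater than both neighbors) of the trace
#' inside the epoch, enforces a minimum inter-peak separation (larger peaks
#' win), and returns the mean of the `k` largest — the epoch activity metric
#' used to compare, e.g., a 5-min baseline against the period after
#' chemogenetic activation. If fewer than `k` peaks exist the mean of all is
#' returned with a warning; with no interior local maxima the result is `NA`
#' with a `reason` attribute.
#'
#' @param trace A [region_trace()].
#' @param epoch `(start_s, end_s)` within the recording.
#' @param k Number of peaks to average (default 20).
#' @param min_separation_s Minimum spacing between retained peaks (s).
#' @return Scalar mean peak dF/F with attributes `peaks` (data.frame of the
#'   retained peak times and values) and, when undefined, `reason`.
#' @export
top_k_peak_mean <- function(trace, epoch, k = 20, min_separation_s = 0.5) {
  stopifnot(k >= 1, length(epoch) == 2, epoch[1] < epoch[2])
  sel <- which(trace$time_s >= epoch[1] & trace$time_s <= epoch[2])
  if (!length(sel)) stop("top_k_peak_mean: epoch contains no frames")
  v <- trace$values[sel]
  t <- trace$time_s[sel]
  m <- length(v)
  if (m < 3) stop("top_k_peak_mean: epoch too short to contain a local maximum")
  is_pk <- which(v[2:(m - 1)] > v[1:(m - 2)] & v[2:(m - 1)] > v[3:m]) + 1
  if (!length(is_pk)) {
    warning("top_k_peak_mean: no interior local maxima in epoch; result undefined")
    return(structure(NA_real_, reason = "no local maxima in epoch",
                     peaks = data.frame(time_s = numeric(0), value = numeric(0))))
  }
  ord <- is_pk[order(v[is_pk], decreasing = TRUE)]
  keep <- integer(0)
  for (i in ord)
    if (!length(keep) || all(abs(t[i] - t[keep]) >= min_separation_s))
      keep <- c(keep, i)
  if (length(keep) < k)
    warning(sprintf("top_k_peak_mean: only %d peak(s) found; averaging all of them",
                    length(keep)))
  top <- keep[seq_len(min(k, length(keep)))]
  structure(mean(v[top]),
            peaks = data.frame(time_s = t[top], value = v[top]))
}
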