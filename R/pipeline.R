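#' Pipeline configuration
#'
#' Gathers every stage parameter with defaults set to the recording and
#' analysis constants the package is built around: 10 Hz frames, 0.1 Hz
#' bleach-correction cutoff, 0.05-2 Hz wavelet segmentation, a 0.1-0.5 Hz
#' band of interest, a +/-3 s peri-event window split into 2 s sub-windows,
#' and 20 peaks for the epoch peak statistic. All defaults are echoed into
#' the provenance log of [run_pipeline()].
#'
#' @param sim A [sim_config()] for the synthetic-session stage (ignored when
#'   `frames_csv` inputs are supplied).
#' @param frames_csv Optional named character vector/list of length 2
#'   (`region1`, `region2`) of frame CSV paths; when given, the simulate
#'   stage is skipped and these files (plus `refs_csv`) are read instead.
#' @param refs_csv Optional CSV of reference curves (columns `wavelength_nm`
#'   then one per fluorophore), required with `frames_csv`.
#' @param events_csv Optional event-table CSV used instead of the simulated
#'   schedule.
#' @param cutoff_hz High-pass bleach-correction cutoff (Hz).
#' @param epsilon Motion-correction small-denominator guard.
#' @param nonnegative Use nonnegative least squares for unmixing?
#' @param bands Wavelet band matrix; see [default_bands()].
#' @param band_of_interest `(f_lo, f_hi)` Hz band reported as the headline
#'   inter-regional correlation.
#' @param omega0,n_voices Morlet parameters.
#' @param window Peri-event window (s).
#' @param top_k Number of peaks for [top_k_peak_mean()].
#' @param seed Session seed (overrides `sim$seed` when not `NULL`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            frames_csv = NULL, refs_csv = NULL,
                            events_csv = NULL,
                            cutoff_hz = 0.1, epsilon = 0.05,
                            nonnegative = FALSE,
                            bands = default_bands(),
                            band_of_interest = c(0.1, 0.5),
                            omega0 = 6, n_voices = 12,
                            window = c(-3, 3), top_k = 20,
                            seed = NULL) {
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  cfg <- list(sim = sim, frames_csv = frames_csv, refs_csv = refs_csv,
              events_csv = events_csv, cutoff_hz = cutoff_hz,
              epsilon = epsilon, nonnegative = nonnegative, bands = bands,
              band_of_interest = band_of_interest, omega0 = omega0,
              n_voices = n_voices, window = window, top_k = top_k)
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  fs <- cfg$sim$frame_rate_hz
  if (any(cfg$bands[, 2] > fs / 2) || cfg$band_of_interest[2] > fs / 2)
    stop("configuration error: a requested band exceeds the Nyquist frequency")
  if (cfg$cutoff_hz <= 0 || fs < 10 * cfg$cutoff_hz)
    stop("configuration error: cutoff_hz must be positive and at most frame_rate/10")
  if (cfg$window[1] >= cfg$window[2])
    stop("configuration error: peri-event window is empty")
  if (!is.null(cfg$frames_csv) && is.null(cfg$refs_csv))
    stop("configuration error: frames_csv requires refs_csv")
  invisible(cfg)
}

# Canonical config hash: md5 of a sorted-key JSON dump.
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

read_refs_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  reference_spectra(t(as.matrix(df[, -1])), df[[1]],
                    fluorophores = names(df)[-1])
}

#' Run the full dual-region photometry pipeline
#'
#' Orchestrates simulate (or load) -> unmix -> preprocess -> band
#' decomposition and correlation -> peri-event analysis -> behavior scoring,
#' with a provenance log (config echo, config hash, seed, package version,
#' per-stage warnings: clip fractions, masked frames, dropped trials,
#' exclusions). Configuration is validated before any computation, so an
#' invalid config fails fast and writes nothing.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, every intermediate artifact
#'   (frames, unmixed coefficients, dF/F traces, band correlations, trial
#'   matrices, cumulative activity, discrimination result, provenance JSON)
#'   is written there as CSV/JSON.
#' @return A list of class `photosync_run`: `dff` (two [region_trace()]s),
#'   `band_cor` (per-band correlation table), `r_band` (the band-of-interest
#'   r), `broadband`, `trials` and `cumact` per region, `behavior`,
#'   `unmixed`, `events`, `truth` (when simulated) and `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  validate_pipeline_config(config)
  notes <- character(0)

  if (is.null(config$frames_csv)) {
    sess <- simulate_session(config$sim)
    frames <- sess$frames
    refs <- sess$refs
    events <- sess$events
    truth <- sess$truth
    notes <- c(notes, sprintf("clip_fraction: %s",
                              paste(sprintf("%s=%.4g", names(truth$clip_fraction),
                                            truth$clip_fraction), collapse = ", ")))
  } else {
    frames <- lapply(config$frames_csv, read_frames_csv)
    names(frames) <- names(config$frames_csv)
    refs <- read_refs_csv(config$refs_csv)
    events <- NULL
    truth <- NULL
  }
  if (!is.null(config$events_csv)) events <- read_events_csv(config$events_csv)

  unmixed <- lapply(frames, unmix_session, refs = refs,
                    nonnegative = config$nonnegative)
  dff <- lapply(unmixed, preprocess_traces, cutoff_hz = config$cutoff_hz,
                epsilon = config$epsilon)

  decomp <- lapply(dff, morlet_decompose, bands = config$bands,
                   omega0 = config$omega0, n_voices = config$n_voices)
  band_cor <- band_correlation_matrix(decomp[[1]], decomp[[2]])
  r_band <- band_r(band_cor, config$band_of_interest)
  broadband <- broadband_correlation(dff[[1]], dff[[2]])

  trials <- cumact <- NULL
  if (!is.null(events) && nrow(events) > 0) {
    trials <- lapply(dff, align_trials, events = events, window = config$window)
    cumact <- lapply(trials, cumulative_activity)
    notes <- c(notes, sprintf("dropped_trials: %s",
                              paste(sprintf("%s=%d", names(trials),
                                            vapply(trials, `[[`, 0L, "n_dropped")),
                                    collapse = ", ")))
  }
  behavior <- NULL
  if (!is.null(events) && nrow(events) > 0) {
    behavior <- discrimination_ratio(events, phase = events$phase[1])
    if (behavior$excluded)
      notes <- c(notes, sprintf("behavior_excluded: %s", behavior$reason))
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("photosync")),
    config_hash = config_hash(config),
    seed = config$sim$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = list(frame_rate_hz = config$sim$frame_rate_hz,
                      cutoff_hz = config$cutoff_hz,
                      bands = config$bands,
                      band_of_interest = config$band_of_interest,
                      window_s = config$window, top_k = config$top_k,
                      epsilon = config$epsilon,
                      omega0 = config$omega0, n_voices = config$n_voices,
                      nonnegative = config$nonnegative),
    notes = notes)

  res <- structure(
    list(dff = dff, band_cor = band_cor, r_band = r_band,
         broadband = broadband, trials = trials, cumact = cumact,
         behavior = behavior, unmixed = unmixed, events = events,
         truth = truth, refs = refs, provenance = provenance),
    class = "photosync_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (rg in names(frames))
      write_frames_csv(frames[[rg]], file.path(out_dir, paste0("frames_", rg, ".csv")))
    for (rg in names(unmixed))
      write_unmixed_csv(unmixed[[rg]], file.path(out_dir, paste0("unmixed_", rg, ".csv")))
    for (rg in names(dff))
      write_trace_csv(dff[[rg]], file.path(out_dir, paste0("dff_", rg, ".csv")))
    utils::write.csv(as.data.frame(band_cor),
                     file.path(out_dir, "band_correlation.csv"), row.names = FALSE)
    if (!is.null(events))
      write_events_csv(events, file.path(out_dir, "events.csv"))
    if (!is.null(cumact))
      for (rg in names(cumact))
        utils::write.csv(as.data.frame(cumact[[rg]]),
                         file.path(out_dir, paste0("cumulative_activity_", rg, ".csv")),
                         row.names = FALSE)
    if (!is.null(behavior))
      utils::write.csv(as.data.frame(behavior),
                       file.path(out_dir, "discrimination.csv"), row.names = FALSE)
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  res
}

#' @export
print.photosync_run <- function(x, ...) {
  cat("<photosync_run>\n")
  cat(sprintf("  band %g-%g Hz inter-regional correlation: R = %.4f\n",
              x$provenance$parameters$band_of_interest[1],
              x$provenance$parameters$band_of_interest[2], x$r_band))
  cat(sprintf("  broadband dF/F correlation: R = %.4f (p = %.3g)\n",
              x$broadband$r, x$broadband$p_value))
  if (!is.null(x$cumact)) {
    for (rg in names(x$cumact)) {
      s <- attr(x$cumact[[rg]], "summary")
      cat(sprintf("  %s cumulative activity (dF/F*s): pre %.3f, exploring %.3f, post %.3f\n",
                  rg, s["pre", "mean"], s["exploring", "mean"], s["post", "mean"]))
    }
  }
  if (!is.null(x$behavior)) {
    if (x$behavior$excluded)
      cat(sprintf("  behavior: excluded (%s)\n", x$behavior$reason))
    else
      cat(sprintf("  behavior (%s): discrimination ratio %.3f (novel %.1f s, old %.1f s)\n",
                  x$behavior$phase, x$behavior$ratio,
                  x$behavior$time_novel_s, x$behavior$time_old_s))
  }
  cat(sprintf("  seed %d, config %s\n", x$provenance$seed, x$provenance$config_hash))
  invisible(x)
}
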