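# Pearson r with the standard t-based two-sided p-value on n - 2 df.
pearson_r <- function(a, b) {
  n <- length(a)
  if (n < 3) return(list(r = NA_real_, n = n, p = NA_real_,
                         reason = "fewer than 3 valid frames"))
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(list(r = NA_real_, n = n, p = NA_real_, reason = "zero-variance input"))
  r <- stats::cor(a, b)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  list(r = r, n = n, p = 2 * stats::pt(-abs(tt), n - 2), reason = NA_character_)
}

#' Band-wise inter-regional correlation matrix
#'
#' Pearson correlation between two regions' band components, one coefficient
#' per frequency band, computed over the frames outside both decompositions'
#' cones of influence. Bands with fewer than 3 valid frames or degenerate
#' components are reported as undefined with a reason.
#'
#' @param decomp_a,decomp_b [morlet_decompose()] results for the two regions,
#'   on identical bands and clocks.
#' @return A `data.frame` (class `band_correlation`) with columns
#'   `band_lo_hz`, `band_hi_hz`, `r`, `n`, `p`, `reason`.
#' @export
band_correlation_matrix <- function(decomp_a, decomp_b) {
  if (!isTRUE(all.equal(decomp_a$bands, decomp_b$bands)))
    stop("band_correlation_matrix: decompositions use different bands")
  if (ncol(decomp_a$components) != ncol(decomp_b$components) ||
      abs(decomp_a$frame_rate_hz - decomp_b$frame_rate_hz) > 1e-9)
    stop("band_correlation_matrix: decompositions are not on the same clock")
  nb <- nrow(decomp_a$bands)
  out <- lapply(seq_len(nb), function(b) {
    ok <- decomp_a$coi_valid[b, ] & decomp_b$coi_valid[b, ]
    pr <- pearson_r(decomp_a$components[b, ok], decomp_b$components[b, ok])
    data.frame(band_lo_hz = decomp_a$bands[b, 1], band_hi_hz = decomp_a$bands[b, 2],
               r = pr$r, n = pr$n, p = pr$p, reason = pr$reason,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, out), class = c("band_correlation", "data.frame"))
}

#' Look up one band's correlation
#'
#' @param bc A [band_correlation_matrix()] result.
#' @param band `(f_lo, f_hi)` in Hz.
#' @return The Pearson `r` for the matching band row.
#' @export
band_r <- function(bc, band = c(0.1, 0.5)) {
  i <- which(abs(bc$band_lo_hz - band[1]) < 1e-9 & abs(bc$band_hi_hz - band[2]) < 1e-9)
  if (!length(i)) stop("band_r: requested band not present in the correlation table")
  bc$r[i]
}

#' Broadband Pearson correlation of two traces
#'
#' Correlation of the full (or trial-averaged, at the caller's choice) dF/F
#' traces of two regions, as used for session-level and task-phase
#' correlations.
#'
#' @param trace_a,trace_b [region_trace()]s on the same clock, or plain
#'   numeric vectors of equal length (e.g. trial-averaged peri-event traces).
#' @param label Free-text provenance recorded in the result (what the inputs
#'   were: full traces vs trial averages).
#' @return A list of class `correlation_result`: `r`, `n_samples`, `p_value`,
#'   `band = "broadband"`, `label`, and `reason` when undefined.
#' @export
broadband_correlation <- function(trace_a, trace_b, label = "full_trace") {
  a <- if (inherits(trace_a, "region_trace")) trace_a$values else as.numeric(trace_a)
  b <- if (inherits(trace_b, "region_trace")) trace_b$values else as.numeric(trace_b)
  if (inherits(trace_a, "region_trace") && inherits(trace_b, "region_trace"))
    check_same_clock(trace_a, trace_b)
  if (length(a) != length(b)) stop("broadband_correlation: inputs differ in length")
  pr <- pearson_r(a, b)
  structure(list(r = pr$r, n_samples = pr$n, p_value = pr$p,
                 band = "broadband", label = label, reason = pr$reason),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  if (is.na(x$r)) {
    cat(sprintf("<correlation_result> undefined (%s), n = %d [%s]\n",
                x$reason, x$n_samples, x$label))
  } else {
    cat(sprintf("<correlation_result> R = %.4f, n = %d, p = %.3g (%s, %s)\n",
                x$r, x$n_samples, x$p_value, x$band, x$label))
  }
  invisible(x)
}

#' Compare correlation coefficients between groups via Fisher transform
#'
#' Applies the variance-stabilizing Fisher transform `z = atanh(r)` to each
#' subject's session correlation and compares the two groups with an unpaired
#' two-sample t-test (`df = n1 + n2 - 2`). The subject-level unit is one
#' animal's session r, not per-frame samples.
#'
#' @param r_group1,r_group2 Numeric vectors of per-subject Pearson r, all
#'   strictly inside (-1, 1), at least 2 per group.
#' @return A list of class `group_comparison`: `z_group1`, `z_group2`,
#'   `t_statistic`, `degrees_of_freedom`, `p_value`, and back-transformed
#'   group mean correlations `mean_r`.
#' @export
fisher_compare_groups <- function(r_group1, r_group2) {
  for (r in list(r_group1, r_group2)) {
    if (length(r) < 2) stop("fisher_compare_groups: each group needs at least 2 subjects")
    if (any(abs(r) >= 1)) stop("fisher_compare_groups: |r| = 1 gives infinite z; cannot compare")
  }
  z1 <- atanh(r_group1); z2 <- atanh(r_group2)
  df <- length(z1) + length(z2) - 2
  if (stats::sd(c(z1, z2)) == 0) {
    # all z identical: no between-group difference by definition
    tt <- list(statistic = 0, parameter = df, p.value = 1)
  } else {
    tt <- stats::t.test(z1, z2, var.equal = TRUE)
  }
  structure(list(z_group1 = z1, z_group2 = z2,
                 t_statistic = unname(tt$statistic),
                 degrees_of_freedom = unname(tt$parameter),
                 p_value = tt$p.value,
                 mean_r = c(group1 = tanh(mean(z1)), group2 = tanh(mean(z2)))),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> mean R: %.4f vs %.4f; t(%d) = %.4f, p = %.4g (unpaired t on Fisher z)\n",
              x$mean_r[1], x$mean_r[2], x$degrees_of_freedom,
              x$t_statistic, x$p_value))
  invisible(x)
}
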