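#' Apply the exploration exclusion rules
#'
#' A session is excluded when the animal did not explore one object at all
#' (either bout count is zero) or explored both objects fewer than three
#' times (both counts below 3; the conjunctive reading of the criterion).
#' `strict = TRUE` switches to the stricter disjunctive reading, excluding
#' when either count is below 3. The first matching rule is reported.
#'
#' @param events An [event_table()] (already filtered to one phase, if
#'   applicable).
#' @param strict Use the either-below-three rule instead of both-below-three?
#' @return A list: `excluded` (flag), `reason` (string or `NA`),
#'   `n_bouts_novel`, `n_bouts_old`.
#' @export
apply_exclusion <- function(events, strict = FALSE) {
  n_nov <- sum(events$object == "novel")
  n_old <- sum(events$object == "old")
  excluded <- FALSE; reason <- NA_character_
  if (n_nov == 0 || n_old == 0) {
    excluded <- TRUE
    reason <- "did not explore one object at all"
  } else if (!strict && n_nov < 3 && n_old < 3) {
    excluded <- TRUE
    reason <- "explored both objects fewer than three times"
  } else if (strict && (n_nov < 3 || n_old < 3)) {
    excluded <- TRUE
    reason <- "explored an object fewer than three times (strict rule)"
  }
  list(excluded = excluded, reason = reason,
       n_bouts_novel = n_nov, n_bouts_old = n_old)
}

#' Novel-place discrimination ratio
#'
#' `DR = (time at novel - time at old) / (time at old + time at novel)`,
#' where exploration time per object is the summed bout duration. Zero means
#' no preference; positive values mean preferential exploration of the novel
#' configuration (memory of the familiar one). Sessions failing the
#' exclusion rules get `ratio = NA` with the reason recorded.
#'
#' @param events An [event_table()].
#' @param phase Which task phase to score (`"retrieval"` or `"encoding"`).
#' @param strict_exclusion Passed to [apply_exclusion()].
#' @return A one-row `data.frame` (class `discrimination_result`):
#'   `phase`, `time_novel_s`, `time_old_s`, `n_bouts_novel`, `n_bouts_old`,
#'   `ratio`, `excluded`, `reason`.
#' @export
discrimination_ratio <- function(events, phase = c("retrieval", "encoding"),
                                 strict_exclusion = FALSE) {
  phase <- match.arg(phase)
  ev <- events[events$phase == phase, , drop = FALSE]
  dur <- ev$offset_s - ev$onset_s
  t_nov <- sum(dur[ev$object == "novel"])
  t_old <- sum(dur[ev$object == "old"])
  excl <- apply_exclusion(ev, strict = strict_exclusion)
  ratio <- if (excl$excluded) NA_real_ else (t_nov - t_old) / (t_nov + t_old)
  structure(
    data.frame(phase = phase, time_novel_s = t_nov, time_old_s = t_old,
               n_bouts_novel = excl$n_bouts_novel,
               n_bouts_old = excl$n_bouts_old,
               ratio = ratio, excluded = excl$excluded, reason = excl$reason,
               stringsAsFactors = FALSE),
    class = c("discrimination_result", "data.frame"))
}

#' Group statistics on discrimination ratios
#'
#' Per group, a one-sample t-test against chance performance (zero); between
#' groups, an unpaired two-sample t-test. All tests two-sided.
#'
#' @param group1,group2 Numeric vectors of non-excluded subjects'
#'   discrimination ratios, at least 2 per group.
#' @return A list: `one_sample` (per-group `t`, `df`, `p`, `mean`) and
#'   `two_sample` (`t`, `df`, `p`).
#' @export
group_ratio_tests <- function(group1, group2) {
  for (g in list(group1, group2))
    if (length(g) < 2) stop("group_ratio_tests: each group needs at least 2 subjects")
  one <- lapply(list(group1 = group1, group2 = group2), function(g) {
    if (stats::sd(g) == 0) {
      # all-identical group: t is 0 when the mean is at chance, else infinite
      list(t = if (mean(g) == 0) 0 else sign(mean(g)) * Inf,
           df = length(g) - 1, p = if (mean(g) == 0) 1 else 0, mean = mean(g))
    } else {
      tt <- stats::t.test(g, mu = 0)
      list(t = unname(tt$statistic), df = unname(tt$parameter),
           p = tt$p.value, mean = mean(g))
    }
  })
  if (stats::sd(c(group1, group2)) == 0) {
    two <- list(t = 0, df = length(group1) + length(group2) - 2, p = 1)
  } else {
    tt2 <- stats::t.test(group1, group2, var.equal = TRUE)
    two <- list(t = unname(tt2$statistic), df = unname(tt2$parameter),
                p = tt2$p.value)
  }
  list(one_sample = one, two_sample = two)
}
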