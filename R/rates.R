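#' Condition-specific firing rate of a unit
#'
#' Mean spike count over trials matching a condition selector, divided by
#' the counting-window length.
#'
#' @param trials A trial table from [build_trials()].
#' @param unit_id Unit column name.
#' @param laser_on Optional logical filter on the laser state.
#' @param locomotion Optional filter, `"still"` or `"running"`.
#' @return Firing rate in Hz.
#' @export
condition_rate <- function(trials, unit_id, laser_on = NULL,
                           locomotion = NULL) {
  sel <- rep(TRUE, nrow(trials))
  if (!is.null(laser_on)) sel <- sel & trials$laser_on == laser_on
  if (!is.null(locomotion)) sel <- sel & trials$locomotion == locomotion
  if (!any(sel)) {
    abort(sprintf("no trials match selector (laser_on=%s, locomotion=%s)",
                  deparse(laser_on), deparse(locomotion)))
  }
  if (!unit_id %in% names(trials)) {
    abort(sprintf("no such unit column: %s", unit_id))
  }
  mean(trials[[unit_id]][sel]) / attr(trials, "window_length")
}

#' Laser-on / laser-off firing-rate ratio
#'
#' Ratio of the unit's mean evoked rate with the laser on to its rate with
#' the laser off, at a fixed locomotion state. Units silent with the laser
#' off have an undefined ratio and return `NA` with a warning.
#'
#' @inheritParams condition_rate
#' @param locomotion Locomotion state at which to compare (default
#'   `"still"`).
#' @return Dimensionless ratio, or `NA` if the laser-off rate is zero.
#' @export
laser_rate_ratio <- function(trials, unit_id, locomotion = "still") {
  off <- condition_rate(trials, unit_id, laser_on = FALSE,
                        locomotion = locomotion)
  on <- condition_rate(trials, unit_id, laser_on = TRUE,
                       locomotion = locomotion)
  if (off == 0) {
    warn(sprintf("unit %s: laser-off rate is zero; ratio undefined", unit_id))
    return(NA_real_)
  }
  on / off
}

#' Laser rate ratios for all units
#'
#' @inheritParams laser_rate_ratio
#' @return Tibble with `unit_id`, `locomotion`, `rate_off`, `rate_on`,
#'   `ratio`.
#' @export
laser_rate_ratios <- function(trials, locomotion = "still") {
  ids <- attr(trials, "unit_ids")
  purrr::map_dfr(ids, function(id) {
    off <- condition_rate(trials, id, laser_on = FALSE, locomotion = locomotion)
    on <- condition_rate(trials, id, laser_on = TRUE, locomotion = locomotion)
    tibble::tibble(unit_id = id, locomotion = locomotion,
                   rate_off = off, rate_on = on,
                   ratio = ifelse(off > 0, on / off, NA_real_))
  })
}

#' Evoked / baseline firing-rate ratio
#'
#' Visually evoked rate at the unit's optimal grating direction (the
#' direction with the highest evoked mean rate; ties broken toward the
#' lowest direction) divided by the mean rate in a window of the same trials
#' immediately preceding stimulus onset.
#'
#' @param session A [session()].
#' @param unit_id Unit id in the session.
#' @param trials Trial table for the session (supplies windows/conditions).
#' @param pre_window Baseline window length before onset, seconds.
#' @param laser_on Restrict to one laser state (default `FALSE`).
#' @return A one-row tibble with `unit_id`, `optimal_direction`,
#'   `evoked_rate`, `baseline_rate`, `ratio` (`NA` with a warning if the
#'   baseline is silent).
#' @export
evoked_baseline_ratio <- function(session, unit_id, trials,
                                  pre_window = 0.5, laser_on = FALSE) {
  stopifnot(inherits(session, "optovis_session"))
  if (!unit_id %in% names(trials)) {
    abort(sprintf("no such unit column: %s", unit_id))
  }
  sub <- trials[trials$laser_on == laser_on, , drop = FALSE]
  if (nrow(sub) == 0) abort("no trials in the requested laser state")
  wl <- attr(trials, "window_length")
  by_dir <- tapply(sub[[unit_id]], sub$direction, mean) / wl
  best <- as.numeric(names(by_dir))[which.max(by_dir)]  # which.max: first max
  best_rows <- sub[sub$direction == best, , drop = FALSE]
  evoked <- mean(best_rows[[unit_id]]) / wl

  u <- session$units[[match(unit_id,
                            vapply(session$units, `[[`, character(1),
                                   "unit_id"))]]
  if (is.null(u)) abort(sprintf("unit %s not found in session", unit_id))
  pre_counts <- vapply(best_rows$onset, function(on) {
    sum(u$spike_times >= on - pre_window & u$spike_times < on)
  }, numeric(1))
  baseline <- mean(pre_counts) / pre_window
  if (baseline == 0) {
    warn(sprintf("unit %s: zero baseline rate; ratio undefined", unit_id))
  }
  tibble::tibble(unit_id = unit_id, optimal_direction = best,
                 evoked_rate = evoked, baseline_rate = baseline,
                 ratio = ifelse(baseline > 0, evoked / baseline, NA_real_))
}

#' Coefficient of variation of per-trial firing rates
#'
#' Sample standard deviation (n-1 denominator) divided by the mean; a
#' measure of response reliability across trials. Scale-invariant.
#'
#' @param rates Numeric vector of per-trial firing rates (Hz), length >= 2.
#' @return Dimensionless CV, or `NA` with a warning if the mean is zero.
#' @export
coefficient_of_variation <- function(rates) {
  if (length(rates) < 2) abort("need at least 2 trials")
  m <- mean(rates)
  if (m == 0) {
    warn("zero mean rate; CV undefined")
    return(NA_real_)
  }
  sd(rates) / m
}
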