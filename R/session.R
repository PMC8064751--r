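#' Recording session container
#'
#' A `session` bundles everything one head-fixed recording produces: the
#' multichannel LFP with electrode depths, sorted units (spike times plus mean
#' waveforms), the running-speed trace, and the stimulus and laser event
#' schedules. All times are seconds from recording start; depths are
#' micrometres below the pia, positive downward.
#'
#' @param subject_id Character scalar identifying the animal.
#' @param region Recording site, `"V1"` or `"dLGN"`.
#' @param opsin Construct expressed in the perturbed neurons: `"ChR2"`
#'   (excitatory), `"eNpHR"` (inhibitory) or `"eYFP"` (control, no opsin).
#' @param lfp Numeric matrix, channels x samples, in microvolts. May have zero
#'   rows when no LFP was kept.
#' @param lfp_rate Sampling rate of `lfp` in Hz. Must exceed 600 Hz so that
#'   the highest analysis frequency (300 Hz) is below Nyquist.
#' @param channel_depths Numeric vector, micrometres below pia, one per LFP
#'   channel.
#' @param channel_shank Integer vector, shank id per channel (depths must be
#'   monotone within a shank).
#' @param units List of objects created by [unit()].
#' @param speed Tibble with columns `t` (s) and `v` (cm/s, non-negative) on a
#'   uniform time grid, as produced by [integrate_speed()].
#' @param stimulus_events Tibble with columns `onset`, `duration`, `kind`
#'   (`grating`, `gray`, `checkerboard`, `noise`), `direction` (degrees in
#'   [0, 360), `NA` unless `kind == "grating"`), `spatial_freq` (cycles/deg)
#'   and `temporal_freq` (Hz).
#' @param laser_events Tibble with columns `onset` and `duration` (s);
#'   events must not overlap.
#' @param duration Total recording span in seconds. Defaults to the latest
#'   event/sample time.
#'
#' @return An object of class `"optovis_session"`.
#' @seealso [unit()], [build_trials()], [generate_session()],
#'   [read_session()], [write_session()]
#' @export
session <- function(subject_id,
                    region = c("V1", "dLGN"),
                    opsin = c("ChR2", "eNpHR", "eYFP"),
                    lfp = matrix(numeric(), nrow = 0, ncol = 0),
                    lfp_rate = 1000,
                    channel_depths = numeric(),
                    channel_shank = rep(1L, length(channel_depths)),
                    units = list(),
                    speed = tibble::tibble(t = numeric(), v = numeric()),
                    stimulus_events = empty_stimulus_events(),
                    laser_events = tibble::tibble(onset = numeric(),
                                                  duration = numeric()),
                    duration = NULL) {
  region <- match.arg(region)
  opsin <- match.arg(opsin)
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  lfp <- as.matrix(lfp)
  if (nrow(lfp) > 0 && lfp_rate <= 2 * 300) {
    abort("`lfp_rate` must exceed 600 Hz (twice the 300 Hz analysis ceiling).")
  }
  if (nrow(lfp) != length(channel_depths)) {
    abort("`channel_depths` must have one entry per LFP channel.")
  }
  if (length(channel_shank) != length(channel_depths)) {
    abort("`channel_shank` must have one entry per LFP channel.")
  }
  for (sh in unique(channel_shank)) {
    d <- channel_depths[channel_shank == sh]
    if (is.unsorted(d) && is.unsorted(rev(d))) {
      abort(sprintf("channel_depths must be monotone within shank %s", sh))
    }
  }
  if (any(speed$v < 0)) abort("speed values must be >= 0")
  stimulus_events <- validate_stimulus_events(stimulus_events)
  laser_events <- validate_laser_events(laser_events)
  ok <- vapply(units, inherits, logical(1), what = "optovis_unit")
  if (!all(ok)) abort("`units` must be a list of unit() objects.")

  span_candidates <- c(
    if (nrow(lfp) > 0) ncol(lfp) / lfp_rate else 0,
    if (nrow(speed) > 0) max(speed$t) else 0,
    if (nrow(stimulus_events) > 0)
      max(stimulus_events$onset + stimulus_events$duration) else 0,
    if (nrow(laser_events) > 0)
      max(laser_events$onset + laser_events$duration) else 0,
    vapply(units, function(u) if (length(u$spike_times)) max(u$spike_times) else 0,
           numeric(1))
  )
  duration <- duration %||% max(c(span_candidates, 0))
  if (nrow(stimulus_events) > 0 &&
      max(stimulus_events$onset + stimulus_events$duration) > duration + 1e-9) {
    abort("stimulus events extend past the recording span")
  }
  if (nrow(laser_events) > 0 &&
      max(laser_events$onset + laser_events$duration) > duration + 1e-9) {
    abort("laser events extend past the recording span")
  }

  structure(
    list(
      subject_id = subject_id, region = region, opsin = opsin,
      lfp = lfp, lfp_rate = lfp_rate,
      channel_depths = as.numeric(channel_depths),
      channel_shank = as.integer(channel_shank),
      units = units, speed = speed,
      stimulus_events = stimulus_events, laser_events = laser_events,
      duration = duration
    ),
    class = "optovis_session"
  )
}

#' Sorted unit
#'
#' One isolated (or multi-) unit: its spike times, mean waveform, home
#' channel and sort class.
#'
#' @param unit_id Character scalar.
#' @param spike_times Numeric vector of spike times in seconds, sorted
#'   non-decreasing, all `>= 0`.
#' @param mean_waveform Numeric vector, mean spike waveform in microvolts
#'   sampled at `waveform_rate`; must have a unique global minimum (the
#'   trough) so waveform features are well defined.
#' @param waveform_rate Waveform sampling rate in Hz.
#' @param channel_index 1-based index of the channel the unit was sorted on.
#' @param sort_class `"SU"`, `"MU"` or `"unknown"`.
#'
#' @return An object of class `"optovis_unit"`.
#' @export
unit <- function(unit_id, spike_times, mean_waveform = numeric(),
                 waveform_rate = 20000, channel_index = 1L,
                 sort_class = c("unknown", "SU", "MU")) {
  sort_class <- match.arg(sort_class)
  spike_times <- as.numeric(spike_times)
  if (length(spike_times) && (is.unsorted(spike_times) || any(spike_times < 0))) {
    abort(sprintf("unit %s: spike_times must be sorted and >= 0", unit_id))
  }
  if (length(mean_waveform) &&
      sum(mean_waveform == min(mean_waveform)) != 1L) {
    abort(sprintf("unit %s: mean_waveform must have a unique trough", unit_id))
  }
  structure(
    list(unit_id = as.character(unit_id), spike_times = spike_times,
         mean_waveform = as.numeric(mean_waveform),
         waveform_rate = waveform_rate,
         channel_index = as.integer(channel_index),
         sort_class = sort_class),
    class = "optovis_unit"
  )
}

empty_stimulus_events <- function() {
  tibble::tibble(onset = numeric(), duration = numeric(),
                 kind = character(), direction = numeric(),
                 spatial_freq = numeric(), temporal_freq = numeric())
}

validate_stimulus_events <- function(ev) {
  ev <- tibble::as_tibble(ev)
  needed <- c("onset", "duration", "kind")
  if (!all(needed %in% names(ev))) {
    abort("stimulus_events needs columns onset, duration, kind")
  }
  if (!"direction" %in% names(ev)) ev$direction <- NA_real_
  if (!"spatial_freq" %in% names(ev)) ev$spatial_freq <- NA_real_
  if (!"temporal_freq" %in% names(ev)) ev$temporal_freq <- NA_real_
  if (nrow(ev) == 0) return(ev)
  if (any(ev$duration <= 0)) abort("stimulus durations must be > 0")
  bad <- !ev$kind %in% c("grating", "gray", "checkerboard", "noise")
  if (any(bad)) abort("unknown stimulus kind")
  is_grating <- ev$kind == "grating"
  if (any(is_grating & (is.na(ev$direction) | ev$direction < 0 |
                        ev$direction >= 360))) {
    abort("gratings need a direction in [0, 360)")
  }
  if (any(!is_grating & !is.na(ev$direction))) {
    abort("direction is defined only for gratings")
  }
  ev[order(ev$onset), , drop = FALSE]
}

validate_laser_events <- function(ev) {
  ev <- tibble::as_tibble(ev)
  if (!all(c("onset", "duration") %in% names(ev))) {
    abort("laser_events needs columns onset, duration")
  }
  if (nrow(ev) == 0) return(ev)
  if (any(ev$duration <= 0)) abort("laser durations must be > 0")
  ev <- ev[order(ev$onset), , drop = FALSE]
  offs <- ev$onset + ev$duration
  if (nrow(ev) > 1 && any(ev$onset[-1] < offs[-nrow(ev)] - 1e-12)) {
    abort("laser events must not overlap")
  }
  ev
}

#' @export
print.optovis_session <- function(x, ...) {
  cat(sprintf("<optovis_session> %s  region=%s opsin=%s\n",
              x$subject_id, x$region, x$opsin))
  cat(sprintf("  duration %.1f s | %d LFP channel(s) @ %g Hz | %d unit(s)\n",
              x$duration, nrow(x$lfp), x$lfp_rate, length(x$units)))
  cat(sprintf("  %d stimulus event(s), %d laser event(s), %d speed sample(s)\n",
              nrow(x$stimulus_events), nrow(x$laser_events), nrow(x$speed)))
  invisible(x)
}

#' @export
print.optovis_unit <- function(x, ...) {
  cat(sprintf("<optovis_unit> %s: %d spikes, channel %d, %s\n",
              x$unit_id, length(x$spike_times), x$channel_index, x$sort_class))
  invisible(x)
}
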