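#' Locomotion segmentation settings
#'
#' Running speed is integrated over short bins and each trial is labelled
#' `running` when its mean speed is strictly above a per-experiment threshold.
#' The threshold varies across experiments with tracker noise (typical range
#' 1-3 cm/s); the default sits at the midpoint of that range.
#'
#' @param bin_length Integration bin for the speed trace, seconds.
#' @param speed_threshold Running threshold in cm/s; strictly-greater rule.
#'
#' @return A list of class `"locomotion_config"`.
#' @export
locomotion_config <- function(bin_length = 0.1, speed_threshold = 2.0) {
  if (bin_length <= 0) abort("`bin_length` must be > 0")
  if (speed_threshold <= 0) abort("`speed_threshold` must be > 0")
  structure(list(bin_length = bin_length, speed_threshold = speed_threshold),
            class = "locomotion_config")
}

#' Integrate displacement events into a uniform speed trace
#'
#' Converts event-driven ball-tracker output (timestamped physical
#' displacements of the ball surface) into a uniformly sampled speed trace:
#' each bin's speed is the total displacement falling in the bin divided by
#' the bin length. Bins without events read 0 cm/s.
#'
#' @param events Tibble or data frame with columns `t` (s, sorted ascending)
#'   and `displacement` (cm, non-negative).
#' @param bin_length Bin length in seconds (default 0.1 s).
#' @param total_duration Span of the output trace in seconds; defaults to the
#'   last event time rounded up to a whole bin. Must be given when `events`
#'   is empty.
#'
#' @return A tibble with columns `t` (bin start, s) and `v` (cm/s).
#' @examples
#' integrate_speed(data.frame(t = 0.05, displacement = 0.2),
#'                 bin_length = 0.1, total_duration = 0.3)
#' @export
integrate_speed <- function(events, bin_length = 0.1, total_duration = NULL) {
  if (bin_length <= 0) abort("`bin_length` must be > 0")
  events <- tibble::as_tibble(events)
  if (nrow(events) > 0) {
    if (!all(c("t", "displacement") %in% names(events))) {
      abort("`events` needs columns t and displacement")
    }
    if (is.unsorted(events$t)) abort("event timestamps must be sorted")
  }
  if (is.null(total_duration)) {
    if (nrow(events) == 0) {
      abort("`total_duration` is required when there are no events")
    }
    total_duration <- max(events$t)
  }
  n_bins <- max(1L, ceiling(total_duration / bin_length - 1e-9))
  v <- numeric(n_bins)
  if (nrow(events) > 0) {
    idx <- pmin(n_bins, floor(events$t / bin_length) + 1L)
    sums <- tapply(events$displacement, idx, sum)
    v[as.integer(names(sums))] <- as.numeric(sums) / bin_length
  }
  tibble::tibble(t = (seq_len(n_bins) - 1L) * bin_length, v = v)
}

#' Classify a time span as still or running
#'
#' A span counts as `running` only when the mean speed over the span is
#' strictly greater than the threshold ("fell above"); a mean exactly at the
#' threshold is `still`.
#'
#' @param t0,t1 Span limits in seconds; must lie within the speed trace.
#' @param speed Speed trace as returned by [integrate_speed()].
#' @param cfg A [locomotion_config()].
#'
#' @return `"still"` or `"running"`.
#' @export
classify_locomotion <- function(t0, t1, speed, cfg = locomotion_config()) {
  if (t1 <= t0) abort("need t1 > t0")
  m <- mean_speed_in_span(t0, t1, speed, cfg)
  if (m > cfg$speed_threshold) "running" else "still"
}

# Mean of the speed trace over [t0, t1); bins are [t, t + bin_length).
mean_speed_in_span <- function(t0, t1, speed, cfg) {
  if (nrow(speed) == 0) {
    abort("speed trace is empty; events are misaligned with the trace")
  }
  bl <- cfg$bin_length
  trace_end <- speed$t[nrow(speed)] + bl
  if (t0 < speed$t[1] - 1e-9 || t1 > trace_end + 1e-9) {
    abort(sprintf(
      "span [%.3f, %.3f] lies outside the speed trace [%.3f, %.3f]; events misaligned",
      t0, t1, speed$t[1], trace_end))
  }
  i0 <- max(1L, floor((t0 - speed$t[1]) / bl) + 1L)
  i1 <- min(nrow(speed), ceiling((t1 - speed$t[1]) / bl - 1e-9))
  mean(speed$v[i0:i1])
}
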