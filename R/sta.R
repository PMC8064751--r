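#' Spike-triggered average of a noise movie
#'
#' Mean of the stimulus frames at fixed lags preceding each spike. With a
#' zero-mean movie, a stimulus-independent unit's STA shrinks toward zero as
#' spikes accumulate, while a linear-nonlinear unit's STA converges to its
#' receptive-field kernel.
#'
#' @param spike_times Spike times, seconds (at least one inside the movie).
#' @param movie Frames x pixels matrix.
#' @param frame_duration Seconds per frame.
#' @param n_lags Number of frame lags (lag 0 = frame containing the spike,
#'   lag k = k frames earlier).
#' @return A list of class `"sta"`: `frames` (n_lags x pixels matrix),
#'   `n_spikes` (spikes contributing per lag), `frame_duration`.
#' @export
spike_triggered_average <- function(spike_times, movie, frame_duration,
                                    n_lags = 1) {
  movie <- as.matrix(movie)
  n_frames <- nrow(movie)
  fi <- floor(spike_times / frame_duration) + 1L
  fi <- fi[fi >= 1L & fi <= n_frames]
  if (length(fi) == 0) abort("no spikes fall within the movie span")
  frames <- matrix(0, n_lags, ncol(movie))
  n_spk <- integer(n_lags)
  for (lag in seq_len(n_lags) - 1L) {
    idx <- fi - lag
    idx <- idx[idx >= 1L]
    n_spk[lag + 1L] <- length(idx)
    frames[lag + 1L, ] <- colMeans(movie[idx, , drop = FALSE])
  }
  structure(list(frames = frames, n_spikes = n_spk,
                 frame_duration = frame_duration), class = "sta")
}

#' Signal-to-noise score of an STA
#'
#' Peak absolute STA amplitude expressed in z-units of the pixel-noise
#' standard deviation expected for that many averaged frames:
#' `score = max |STA| / (pixel_sd / sqrt(n_spikes))`. A flat STA scores near
#' zero; a strong receptive field scores high.
#'
#' @param sta An `"sta"` object.
#' @param pixel_sd Per-frame pixel standard deviation of the movie
#'   (baseline noise level).
#' @param lag Which lag row to score (default 1 = frame of the spike).
#' @return Numeric score.
#' @export
sta_snr_score <- function(sta, pixel_sd, lag = 1) {
  stopifnot(inherits(sta, "sta"))
  se <- pixel_sd / sqrt(sta$n_spikes[lag])
  max(abs(sta$frames[lag, ])) / se
}

#' Classify recordings as single- or multi-unit by STA signal-to-noise
#'
#' Units whose STA stands out from pixel noise by at least `threshold`
#' z-units are labelled SU, the rest MU. The threshold is a free parameter;
#' classification is monotone in it (raising it never converts an MU to SU).
#'
#' @param scores Named numeric vector of [sta_snr_score()] values.
#' @param threshold SNR threshold in z-units (default 5).
#' @return Tibble with `unit_id`, `sta_score`, `sort_class`.
#' @export
classify_su_mu <- function(scores, threshold = 5) {
  tibble::tibble(unit_id = names(scores) %||% as.character(seq_along(scores)),
                 sta_score = as.numeric(scores),
                 sort_class = unname(ifelse(scores >= threshold, "SU", "MU")))
}
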