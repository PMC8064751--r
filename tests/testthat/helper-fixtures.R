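# Shared fixtures and independent oracles used across the test files.

# Minimal hand-built session: two units, a deterministic grating schedule,
# constant-speed trace. Spike times are chosen by the individual tests.
tiny_session <- function(spike_times_1 = c(0.6, 1.4, 1.6),
                         spike_times_2 = numeric(),
                         directions = c(0, 90),
                         stim_onsets = c(0, 4),
                         laser_onsets = numeric(),
                         speed_value = 0,
                         duration = 10) {
  n_bins <- ceiling(duration / 0.1)
  session(
    subject_id = "tiny", region = "V1", opsin = "ChR2",
    units = list(
      unit("u1", spike_times_1),
      unit("u2", spike_times_2)
    ),
    speed = tibble::tibble(t = (seq_len(n_bins) - 1) * 0.1,
                           v = rep(speed_value, n_bins)),
    stimulus_events = tibble::tibble(
      onset = stim_onsets, duration = 2, kind = "grating",
      direction = directions, spatial_freq = 0.04, temporal_freq = 1),
    laser_events = if (length(laser_onsets)) {
      tibble::tibble(onset = laser_onsets, duration = 2)
    } else {
      tibble::tibble(onset = numeric(), duration = numeric())
    },
    duration = duration
  )
}

# Brute-force mutual information by the literal double sum over all cells.
mi_brute_force <- function(counts) {
  n <- sum(counts)
  p <- counts / n
  pr <- rowSums(p)
  ps <- colSums(p)
  total <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (p[i, j] > 0) {
        total <- total + p[i, j] * log2(p[i, j] / (pr[i] * ps[j]))
      }
    }
  }
  total
}

# Brute-force diagonal-Gaussian posterior decision: evaluate the full
# log-posterior of every class with dnorm and take the argmax (first max on
# ties).
diag_gauss_oracle <- function(x, means, vars, priors) {
  lp <- vapply(seq_len(nrow(means)), function(ci) {
    log(priors[ci]) + sum(stats::dnorm(x, means[ci, ], sqrt(vars), log = TRUE))
  }, numeric(1))
  which.max(lp)
}

# Direct periodogram estimate of one-sided PSD integrated over [f1, f2] Hz.
periodogram_band_power <- function(x, fs, f1, f2) {
  n <- length(x)
  X <- fft(x)
  freqs <- (seq_len(n) - 1) * fs / n
  # one-sided density: 2 |X|^2 / (fs * n) on (0, fs/2)
  dens <- 2 * Mod(X)^2 / (fs * n)
  sel <- freqs >= f1 & freqs <= f2 & freqs <= fs / 2
  sum(dens[sel]) * fs / n
}

# Generated sessions for reuse across expensive tests (memoised per seed).
.session_cache <- new.env(parent = emptyenv())
cached_session <- function(seed, n_repeats = 10, pattern_degradation = 0.5,
                           include_lfp = FALSE, ...) {
  key <- paste(seed, n_repeats, pattern_degradation, include_lfp,
               paste(c(...), collapse = "_"), sep = "|")
  if (is.null(.session_cache[[key]])) {
    cfg <- generator_config(seed = seed, n_repeats = n_repeats,
                            pattern_degradation = pattern_degradation, ...)
    .session_cache[[key]] <- generate_session(cfg, include_lfp = include_lfp)
  }
  .session_cache[[key]]
}
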