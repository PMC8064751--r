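#' Spectral analysis configuration
#'
#' @param bandpass_low,bandpass_high Zero-phase Butterworth band edges, Hz
#'   (defaults 1 and 300).
#' @param freq_grid Frequencies (Hz) for the wavelet transform; default 60
#'   log-spaced points over 2-100 Hz.
#' @param alpha 1/f exponent used by [adjust_one_over_f()] (default 2.5).
#' @param wavelet_cycles Width of the complex Morlet wavelet in cycles
#'   (default 7).
#' @return A list of class `"spectral_config"`.
#' @export
spectral_config <- function(bandpass_low = 1, bandpass_high = 300,
                            freq_grid = exp(seq(log(2), log(100),
                                                length.out = 60)),
                            alpha = 2.5, wavelet_cycles = 7) {
  if (bandpass_low <= 0 || bandpass_high <= bandpass_low) {
    abort("need 0 < bandpass_low < bandpass_high")
  }
  if (alpha < 0) abort("`alpha` must be >= 0")
  if (any(diff(freq_grid) <= 0)) abort("`freq_grid` must be increasing")
  structure(list(bandpass_low = bandpass_low, bandpass_high = bandpass_high,
                 freq_grid = freq_grid, alpha = alpha,
                 wavelet_cycles = wavelet_cycles),
            class = "spectral_config")
}

#' Frequency-band definitions
#'
#' Theta 4-8 Hz, beta 15-30 Hz, gamma 30-80 Hz. Band membership in
#' [band_power()] is inclusive at both edges; 30 Hz is counted as the gamma
#' lower edge, and beta is kept disjoint as `[15, 30)`.
#'
#' @return Named list of `c(low, high)` pairs.
#' @export
band_definitions <- function() {
  list(theta = c(4, 8), beta = c(15, 30), gamma = c(30, 80))
}

#' Zero-phase band-pass filter an LFP signal
#'
#' 4th-order Butterworth applied forward and backward
#' ([signal::filtfilt()]), so event alignment is preserved (zero phase) and
#' attenuation outside the band is steep.
#'
#' @param x Numeric vector (one channel) or channels x samples matrix.
#' @param fs Sampling rate, Hz.
#' @param cfg A [spectral_config()].
#' @return Filtered signal, same shape as `x`.
#' @export
lfp_bandpass <- function(x, fs, cfg = spectral_config()) {
  if (cfg$bandpass_high >= fs / 2) {
    abort(sprintf("band edge %g Hz is not below Nyquist (%g Hz)",
                  cfg$bandpass_high, fs / 2))
  }
  bf <- signal::butter(4, c(cfg$bandpass_low, cfg$bandpass_high) / (fs / 2),
                       type = "pass")
  filt1 <- function(v) as.numeric(signal::filtfilt(bf, v))
  if (is.matrix(x)) t(apply(x, 1, filt1)) else filt1(x)
}

# Complex Morlet filterbank response of one signal at one frequency.
# Returns the analytic band signal z(t); any wavelet scaling cancels in
# morlet_power()'s normalisation.
morlet_response <- function(x, fs, f, cycles) {
  sigma_t <- cycles / (2 * pi * f)
  half <- ceiling(4 * sigma_t * fs)
  tk <- (-half:half) / fs
  psi <- exp(2i * pi * f * tk) * exp(-tk^2 / (2 * sigma_t^2))
  n <- length(x)
  nfft <- stats::nextn(n + length(psi) - 1, 2)
  X <- fft(c(x, numeric(nfft - n)))
  H <- fft(c(Conj(rev(psi)), numeric(nfft - length(psi))))
  full <- fft(X * H, inverse = TRUE) / nfft
  z <- full[(length(psi) - half):(length(psi) - half + n - 1)]
  list(z = z, energy = sum(Mod(psi)^2))
}

#' Wavelet power spectrum of a signal window
#'
#' Convolves the signal with complex Morlet wavelets on the configured
#' frequency grid and averages squared coefficient magnitudes over the
#' analysis window. Normalisation is chosen so the value estimates one-sided
#' power spectral density in uV^2/Hz: for each frequency,
#' `P(f) = 2 * mean(|z|^2) / (fs * sum(|psi|^2))`, which makes unit-variance
#' white noise read `2/fs` at every frequency and is independent of wavelet
#' scaling.
#'
#' @param x Numeric vector (single channel) or channels x samples matrix.
#' @param fs Sampling rate, Hz.
#' @param window `c(t0, t1)` in seconds relative to the start of `x`;
#'   defaults to the full signal. Must be at least 3 cycles of the lowest
#'   grid frequency long.
#' @param cfg A [spectral_config()].
#'
#' @return A tibble of class `"power_spectrum"` with columns `channel`,
#'   `freq` (Hz) and `power` (uV^2/Hz), plus attributes `one_over_f_adjusted`
#'   (FALSE), `wavelet_cycles` and `n_trials_averaged` (1).
#' @export
morlet_power <- function(x, fs, window = NULL, cfg = spectral_config()) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  window <- window %||% c(0, n / fs)
  if (window[1] < 0 || window[2] > n / fs + 1e-9 || window[2] <= window[1]) {
    abort("analysis window must lie within the signal")
  }
  f_min <- cfg$freq_grid[1]
  if ((window[2] - window[1]) < 3 / f_min) {
    abort(sprintf(
      "window of %.3f s is shorter than 3 cycles of the lowest frequency (%.3g Hz)",
      window[2] - window[1], f_min))
  }
  i0 <- max(1L, floor(window[1] * fs) + 1L)
  i1 <- min(n, ceiling(window[2] * fs))
  res <- purrr::map_dfr(seq_len(nrow(x)), function(ch) {
    pw <- vapply(cfg$freq_grid, function(f) {
      r <- morlet_response(x[ch, ], fs, f, cfg$wavelet_cycles)
      2 * mean(Mod(r$z[i0:i1])^2) / (fs * r$energy)
    }, numeric(1))
    tibble::tibble(channel = ch, freq = cfg$freq_grid, power = pw)
  })
  new_power_spectrum(res, adjusted = FALSE, cycles = cfg$wavelet_cycles,
                     n_trials = 1L)
}

new_power_spectrum <- function(tbl, adjusted, cycles, n_trials) {
  attr(tbl, "one_over_f_adjusted") <- adjusted
  attr(tbl, "wavelet_cycles") <- cycles
  attr(tbl, "n_trials_averaged") <- n_trials
  class(tbl) <- c("power_spectrum", class(tbl))
  tbl
}

#' Flatten the 1/f background of a power spectrum
#'
#' Multiplies power at each frequency by `f^alpha`, removing an assumed
#' `1/f^alpha` background trend so band comparisons are not dominated by the
#' low-frequency slope. Applying the adjustment twice is refused.
#'
#' @param spec A `power_spectrum` tibble from [morlet_power()].
#' @param alpha 1/f exponent (default 2.5).
#' @return The adjusted spectrum with the `one_over_f_adjusted` flag set.
#' @export
adjust_one_over_f <- function(spec, alpha = 2.5) {
  stopifnot(inherits(spec, "power_spectrum"))
  if (isTRUE(attr(spec, "one_over_f_adjusted"))) {
    abort("spectrum is already 1/f-adjusted; refusing to adjust twice")
  }
  if (any(spec$freq <= 0)) abort("frequencies must be > 0")
  out <- spec
  out$power <- out$power * out$freq^alpha
  attr(out, "one_over_f_adjusted") <- TRUE
  out
}

#' Mean power in a frequency band
#'
#' Averages the spectrum over grid frequencies `f` with
#' `low <= f <= high` (inclusive at both edges), per channel.
#'
#' @param spec A `power_spectrum` tibble.
#' @param band `c(low, high)` in Hz, or a name from [band_definitions()].
#' @return A tibble with columns `channel` and `power`.
#' @export
band_power <- function(spec, band) {
  if (is.character(band)) band <- band_definitions()[[band]]
  if (is.null(band) || length(band) != 2) abort("unknown band")
  sel <- spec$freq >= band[1] & spec$freq <= band[2]
  if (!any(sel)) {
    abort(sprintf("no grid frequency falls in [%g, %g] Hz", band[1], band[2]))
  }
  spec[sel, ] |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(power = mean(.data$power), .groups = "drop")
}

#' Band-power summary across the standard bands
#'
#' @param spec A `power_spectrum` tibble.
#' @return Tibble with columns `channel`, `band`, `power`.
#' @export
band_summary <- function(spec) {
  purrr::imap_dfr(band_definitions(), function(b, nm) {
    dplyr::mutate(band_power(spec, b), band = nm, .before = "power")
  })
}

#' Stimulus-evoked minus ongoing power
#'
#' Averages per-trial spectra taken during the stimulus and subtracts the
#' average of equal-duration pre-stimulus (ongoing) spectra, per channel and
#' frequency. All spectra must share one frequency grid.
#'
#' @param evoked_spectra,ongoing_spectra Lists of `power_spectrum` tibbles
#'   (one per trial).
#' @return A tibble with columns `channel`, `freq`, `power_diff`.
#' @export
evoked_minus_ongoing <- function(evoked_spectra, ongoing_spectra) {
  if (!length(evoked_spectra) || !length(ongoing_spectra)) {
    abort("need at least one spectrum on each side")
  }
  grids <- lapply(c(evoked_spectra, ongoing_spectra), function(s) s$freq)
  if (!all(vapply(grids, function(g) isTRUE(all.equal(g, grids[[1]])),
                  logical(1)))) {
    abort("frequency grids differ between spectra")
  }
  avg <- function(specs) {
    dplyr::bind_rows(specs) |>
      dplyr::group_by(.data$channel, .data$freq) |>
      dplyr::summarise(power = mean(.data$power), .groups = "drop")
  }
  ev <- avg(evoked_spectra)
  og <- avg(ongoing_spectra)
  dplyr::inner_join(ev, og, by = c("channel", "freq"),
                    suffix = c("_evoked", "_ongoing")) |>
    dplyr::mutate(power_diff = .data$power_evoked - .data$power_ongoing) |>
    dplyr::select("channel", "freq", "power_diff")
}

#' Current source density across depth
#'
#' Second spatial difference of the depth-averaged LFP:
#' `CSD_i = -(V_{i-1} - 2 V_i + V_{i+1}) / h^2`, so current sinks are
#' negative. Boundary channels are omitted. Channels must be uniformly
#' spaced (channels sharing a depth should already be averaged within a
#' shank).
#'
#' @param depth_profile Channels x time numeric matrix, ordered by depth.
#' @param depth_spacing Inter-channel spacing `h` in micrometres; checked
#'   against `depths` when both are given.
#' @param depths Optional channel depths (um) used to verify uniform spacing.
#' @return Matrix (channels - 2) x time of CSD values; row names give the
#'   retained channel indices.
#' @export
compute_csd <- function(depth_profile, depth_spacing = NULL, depths = NULL) {
  v <- as.matrix(depth_profile)
  if (nrow(v) < 3) abort("CSD needs at least 3 channels")
  if (!is.null(depths)) {
    dd <- diff(depths)
    if (max(abs(dd - dd[1])) > 1e-6 * abs(dd[1])) {
      abort("channel depths are not uniformly spaced")
    }
    if (is.null(depth_spacing)) depth_spacing <- abs(dd[1])
  }
  if (is.null(depth_spacing) || depth_spacing <= 0) {
    abort("`depth_spacing` must be a positive spacing in um")
  }
  i <- 2:(nrow(v) - 1)
  csd <- -(v[i - 1, , drop = FALSE] - 2 * v[i, , drop = FALSE] +
             v[i + 1, , drop = FALSE]) / depth_spacing^2
  rownames(csd) <- i
  csd
}

#' Condition-resolved gamma-band power of a session
#'
#' Cuts the session LFP into fixed-length windows labelled by locomotion
#' state and laser state, computes the wavelet spectrum of each window, and
#' returns band power per window. This is the workhorse behind the
#' laser/locomotion gamma contrasts.
#'
#' @param session A [session()] with LFP.
#' @param window_length Analysis window length, seconds.
#' @param cfg A [spectral_config()].
#' @param lcfg A [locomotion_config()].
#' @param band Band name or `c(low, high)` (default gamma).
#' @param channels Channel subset (default: all).
#' @param adjust Apply [adjust_one_over_f()] before band averaging.
#' @return Tibble with columns `window_start`, `locomotion`, `laser_on`,
#'   `channel`, `power`.
#' @export
condition_band_power <- function(session, window_length = 4,
                                 cfg = spectral_config(),
                                 lcfg = locomotion_config(),
                                 band = "gamma", channels = NULL,
                                 adjust = FALSE) {
  stopifnot(inherits(session, "optovis_session"))
  if (nrow(session$lfp) == 0) abort("session has no LFP")
  channels <- channels %||% seq_len(nrow(session$lfp))
  fs <- session$lfp_rate
  n <- ncol(session$lfp)
  starts <- seq(0, n / fs - window_length, by = window_length)
  la <- session$laser_events
  # pad each analysed segment by the wavelet support at the lowest frequency
  margin <- 4 * cfg$wavelet_cycles / (2 * pi * cfg$freq_grid[1])
  purrr::map_dfr(starts, function(t0) {
    t1 <- t0 + window_length
    overlap <- if (nrow(la)) {
      pmax(0, pmin(t1, la$onset + la$duration) - pmax(t0, la$onset))
    } else 0
    frac_on <- sum(overlap) / window_length
    if (frac_on > 0.01 && frac_on < 0.99) return(NULL)  # mixed window: drop
    # label windows only when the locomotion state is pure, so condition
    # averages are not diluted by mid-window state changes
    sel_bins <- session$speed$t >= t0 & session$speed$t < t1
    frac_run <- mean(session$speed$v[sel_bins] > lcfg$speed_threshold)
    if (frac_run > 0.1 && frac_run < 0.9) return(NULL)
    state <- if (frac_run >= 0.9) "running" else "still"
    s0 <- max(0, t0 - margin)
    s1 <- min(n / fs, t1 + margin)
    seg <- session$lfp[channels, (floor(s0 * fs) + 1L):floor(s1 * fs),
                       drop = FALSE]
    seg_t0 <- floor(s0 * fs) / fs
    spec <- morlet_power(seg, fs, window = c(t0, t1) - seg_t0, cfg = cfg)
    if (adjust) spec <- adjust_one_over_f(spec, cfg$alpha)
    bp <- band_power(spec, band)
    tibble::tibble(window_start = t0, locomotion = state,
                   laser_on = frac_on >= 0.99,
                   channel = channels[bp$channel], power = bp$power)
  })
}
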