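#' Synthetic-session generator configuration
#'
#' Defines the statistical structure of a generated recording: a drifting
#' grating schedule (directions x repetitions, laser-on trials randomly
#' interleaved), von Mises direction tuning per unit, narrow- vs
#' broad-spiking waveform templates, a two-state locomotion model, and an LFP
#' composed of a 1/f^alpha background plus state-dependent narrow-band gamma.
#'
#' Default effect sizes follow the condition contrasts the analyses are built
#' to detect: laser-on/laser-off rate factors of 0.79 (still) and 0.67
#' (running) for broad-spiking cells and 0.65/0.59 for narrow-spiking cells,
#' a 1.5x gamma power gain with locomotion and a 0.5x gamma power factor
#' under the laser, on a 1/f^2.5 background.
#'
#' @param n_units_bs,n_units_ns Number of broad- and narrow-spiking units
#'   (defaults 20 and 8, i.e. ~30% NS).
#' @param n_directions Number of evenly spaced grating directions (even, so
#'   that 180 degree orientation grouping is exact).
#' @param n_repeats Repetitions per direction per laser condition.
#' @param stim_duration,gap_duration Grating and gray-gap durations, seconds.
#' @param tuning_concentration von Mises concentration kappa of each unit's
#'   direction tuning.
#' @param base_rate_bs,base_rate_ns Mean evoked rate (Hz) across directions,
#'   still + laser-off.
#' @param baseline_fraction Ongoing (gray screen) rate as a fraction of the
#'   evoked mean.
#' @param locomotion_gain Multiplicative rate gain while running.
#' @param opto_rate_factor_bs,opto_rate_factor_ns Named numeric
#'   `c(still=, running=)`: laser-on/laser-off rate factor per state.
#' @param pattern_degradation In `[0, 1]`: fraction by which laser-on tuning
#'   curves are flattened toward their mean at fixed mean rate. 0 = pure rate
#'   scaling, 1 = flat tuning (no stimulus information).
#' @param gamma_center,gamma_bandwidth Centre (Hz) and Gaussian spectral SD
#'   (Hz) of the narrow-band gamma component.
#' @param gamma_amp_still RMS amplitude (uV) of the gamma component, still
#'   and laser-off.
#' @param gamma_run_gain Gamma *power* gain while running.
#' @param gamma_opto_factor Gamma *power* factor while the laser is on.
#' @param stim_gamma_gain Gamma power gain during visual stimulation.
#' @param one_over_f_alpha Spectral exponent of the LFP background.
#' @param one_over_f_rms RMS amplitude (uV) of the background.
#' @param lfp_rate LFP sampling rate, Hz.
#' @param n_channels,channel_spacing LFP channel count and depth spacing (um).
#' @param run_bout_rates Named `c(still_to_run=, run_to_still=)` per-bin
#'   Markov transition probabilities for the locomotion chain.
#' @param speed_bin Speed-trace resolution, seconds.
#' @param waveform_rate Waveform template sampling rate, Hz.
#' @param seed Integer seed; generation is deterministic given the config.
#'
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(n_units_bs = 20, n_units_ns = 8,
                             n_directions = 8, n_repeats = 20,
                             stim_duration = 2, gap_duration = 2,
                             tuning_concentration = 2,
                             base_rate_bs = 10, base_rate_ns = 16,
                             baseline_fraction = 0.3,
                             locomotion_gain = 1.5,
                             opto_rate_factor_bs = c(still = 0.79, running = 0.67),
                             opto_rate_factor_ns = c(still = 0.65, running = 0.59),
                             pattern_degradation = 0.5,
                             gamma_center = 55, gamma_bandwidth = 10,
                             gamma_amp_still = 20,
                             gamma_run_gain = 1.5,
                             gamma_opto_factor = 0.5,
                             stim_gamma_gain = 1.5,
                             one_over_f_alpha = 2.5,
                             one_over_f_rms = 30,
                             lfp_rate = 1000,
                             n_channels = 4, channel_spacing = 50,
                             run_bout_rates = c(still_to_run = 0.01,
                                                run_to_still = 0.02),
                             speed_bin = 0.1,
                             waveform_rate = 20000,
                             seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$n_directions %% 2 != 0) {
    abort("`n_directions` must be even so orientation grouping is exact")
  }
  if (cfg$stim_duration <= 0 || cfg$gap_duration <= 0) {
    abort("infeasible schedule: durations must be > 0")
  }
  rates <- c(cfg$base_rate_bs, cfg$base_rate_ns, cfg$opto_rate_factor_bs,
             cfg$opto_rate_factor_ns, cfg$locomotion_gain,
             cfg$gamma_run_gain, cfg$gamma_opto_factor, cfg$stim_gamma_gain)
  if (any(rates < 0)) abort("rates and factors must be >= 0")
  if (cfg$pattern_degradation < 0 || cfg$pattern_degradation > 1) {
    abort("`pattern_degradation` must lie in [0, 1]")
  }
  structure(cfg, class = "generator_config")
}

# Run code with a private RNG stream; the caller's RNG state is untouched.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Fixed derivation of per-stage child seeds from one parent seed.
derive_seed <- function(seed, stage) {
  (as.integer(seed) * 7919L + stage * 104729L) %% 2147483629L
}

von_mises_shape <- function(theta_deg, pref_deg, kappa) {
  d1 <- (theta_deg - pref_deg) * pi / 180
  d2 <- d1 - pi
  exp(kappa * (cos(d1) - 1)) + 0.5 * exp(kappa * (cos(d2) - 1))
}

# Condition tuning curves on the direction grid for one unit.
# Flattening mixes the curve toward its mean BEFORE the opto scale, so the
# laser changes the response pattern beyond what the rate factor alone does,
# while the laser-on mean stays factor * laser-off mean exactly.
unit_tuning <- function(base_rate, pref, kappa, directions, loco_gain,
                        opto_factor, degradation) {
  f <- von_mises_shape(directions, pref, kappa)
  lam_still_off <- base_rate * f / mean(f)
  curves <- list()
  for (state in c("still", "running")) {
    g <- if (state == "running") loco_gain else 1
    lam_off <- lam_still_off * g
    lam_on <- opto_factor[[state]] *
      ((1 - degradation) * lam_off + degradation * mean(lam_off))
    curves[[paste0(state, "_off")]] <- lam_off
    curves[[paste0(state, "_on")]] <- lam_on
  }
  curves
}

# Gaussian-bump waveform template with trough fixed at -1 after
# normalisation; peak height and trough-to-peak time set the class.
make_waveform <- function(height, ttp_ms, peak_sd_ms, rate) {
  t_ms <- seq(0, 3, by = 1000 / rate)
  t0 <- 1.0
  w <- -exp(-(t_ms - t0)^2 / (2 * 0.10^2)) +
    height * exp(-(t_ms - t0 - ttp_ms)^2 / (2 * peak_sd_ms^2))
  100 * w  # uV scale
}

simulate_locomotion <- function(n_bins, rates) {
  state <- integer(n_bins)  # 0 still, 1 running
  s <- 0L
  u <- runif(n_bins)
  for (i in seq_len(n_bins)) {
    p <- if (s == 0L) rates[["still_to_run"]] else 1 - rates[["run_to_still"]]
    s <- as.integer(u[i] < p)
    state[i] <- s
  }
  v <- ifelse(state == 1L, runif(n_bins, 5, 15), runif(n_bins, 0, 0.5))
  list(state = state, v = v)
}

# 1/f^alpha background: white noise spectrally shaped to f^(-alpha/2)
# amplitude, rescaled to the requested RMS.
shaped_background <- function(n, fs, alpha, rms) {
  w <- rnorm(n)
  W <- fft(w)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)  # fold to [0, fs/2]
  shape <- ifelse(f > 0, f^(-alpha / 2), 0)
  x <- Re(fft(W * shape, inverse = TRUE)) / n
  x * rms / sd(x)
}

# Narrow-band unit-RMS noise centred at fc with Gaussian spectral window.
narrowband_noise <- function(n, fs, fc, bw) {
  g <- rnorm(n)
  G <- fft(g)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)
  win <- exp(-(f - fc)^2 / (2 * bw^2))
  x <- Re(fft(G * win, inverse = TRUE)) / n
  x / sd(x)
}

build_lfp <- function(cfg, total_dur, run_state_bins, speed_bin,
                      laser_events, stim_events) {
  n <- round(total_dur * cfg$lfp_rate)
  tt <- (seq_len(n) - 1) / cfg$lfp_rate
  bin_idx <- pmin(length(run_state_bins), floor(tt / speed_bin) + 1L)
  running <- run_state_bins[bin_idx] == 1L
  laser <- rep(FALSE, n)
  for (i in seq_len(nrow(laser_events))) {
    laser <- laser | (tt >= laser_events$onset[i] &
                      tt < laser_events$onset[i] + laser_events$duration[i])
  }
  stim <- rep(FALSE, n)
  gr <- stim_events[stim_events$kind == "grating", , drop = FALSE]
  for (i in seq_len(nrow(gr))) {
    stim <- stim | (tt >= gr$onset[i] & tt < gr$onset[i] + gr$duration[i])
  }
  # power gains combine multiplicatively; amplitude is the square root
  amp <- cfg$gamma_amp_still *
    sqrt(cfg$gamma_run_gain)^running *
    sqrt(cfg$gamma_opto_factor)^laser *
    sqrt(cfg$stim_gamma_gain)^stim
  lfp <- matrix(0, nrow = cfg$n_channels, ncol = n)
  for (ch in seq_len(cfg$n_channels)) {
    bg <- shaped_background(n, cfg$lfp_rate, cfg$one_over_f_alpha,
                            cfg$one_over_f_rms)
    gm <- narrowband_noise(n, cfg$lfp_rate, cfg$gamma_center,
                           cfg$gamma_bandwidth)
    lfp[ch, ] <- bg + amp * gm
  }
  lfp
}

poisson_spikes <- function(rate, t0, t1) {
  if (rate <= 0 || t1 <= t0) return(numeric())
  k <- rpois(1, rate * (t1 - t0))
  if (k == 0) return(numeric())
  sort(runif(k, t0, t1))
}

#' Generate a synthetic recording session with known ground truth
#'
#' Produces a full grating session: `n_directions x n_repeats` presentations
#' per laser condition in randomly interleaved order, each
#' `stim_duration` long and followed by a `gap_duration` gray period, with
#' laser pulses coupled to stimulus onset on laser trials. Unit spike trains
#' are inhomogeneous Poisson draws from condition-specific tuning curves
#' (locomotion gain while running; rate scaling plus tuning flattening under
#' the laser). The LFP is a 1/f^alpha background plus narrow-band gamma whose
#' power follows locomotion, laser and stimulus state. The returned ground
#' truth records every condition tuning curve, the gamma amplitudes and each
#' unit's cell class, for parameter-recovery tests.
#'
#' @param cfg A [generator_config()].
#' @param include_lfp Set `FALSE` to skip LFP synthesis (fast spiking-only
#'   sessions for rate/information/decoding work).
#'
#' @return A list with elements `session` (an [session()]) and `truth`
#'   (class `"optovis_ground_truth"`: tibbles `units` and `tuning`, the
#'   gamma condition table, and the config).
#' @export
generate_session <- function(cfg = generator_config(), include_lfp = TRUE) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(derive_seed(cfg$seed, 1L), {
    directions <- seq(0, 360 - 360 / cfg$n_directions,
                      by = 360 / cfg$n_directions)
    per_cond <- rep(directions, each = cfg$n_repeats)
    trial_dir <- c(per_cond, per_cond)
    trial_laser <- c(rep(FALSE, length(per_cond)), rep(TRUE, length(per_cond)))
    ord <- sample.int(length(trial_dir))
    trial_dir <- trial_dir[ord]
    trial_laser <- trial_laser[ord]
    n_trials <- length(trial_dir)

    block <- cfg$stim_duration + cfg$gap_duration
    onsets <- cfg$gap_duration + (seq_len(n_trials) - 1) * block
    total_dur <- cfg$gap_duration + n_trials * block

    stim_events <- tibble::tibble(
      onset = onsets, duration = cfg$stim_duration, kind = "grating",
      direction = trial_dir, spatial_freq = 0.04, temporal_freq = 1)
    laser_events <- tibble::tibble(
      onset = onsets[trial_laser], duration = cfg$stim_duration)

    loco <- simulate_locomotion(ceiling(total_dur / cfg$speed_bin),
                                cfg$run_bout_rates)
    speed <- tibble::tibble(
      t = (seq_along(loco$v) - 1) * cfg$speed_bin, v = loco$v)
    lcfg <- locomotion_config(bin_length = cfg$speed_bin)
    trial_state <- vapply(seq_len(n_trials), function(i) {
      classify_locomotion(onsets[i], onsets[i] + cfg$stim_duration, speed, lcfg)
    }, character(1))

    n_units <- cfg$n_units_bs + cfg$n_units_ns
    cell_class <- c(rep("BS", cfg$n_units_bs), rep("NS", cfg$n_units_ns))
    unit_ids <- sprintf("u%02d_%s", seq_len(n_units), tolower(cell_class))
    pref <- runif(n_units, 0, 360)

    truth_tuning <- list()
    units <- vector("list", n_units)
    for (j in seq_len(n_units)) {
      is_bs <- cell_class[j] == "BS"
      base <- if (is_bs) cfg$base_rate_bs else cfg$base_rate_ns
      fac <- if (is_bs) cfg$opto_rate_factor_bs else cfg$opto_rate_factor_ns
      curves <- unit_tuning(base, pref[j], cfg$tuning_concentration,
                            directions, cfg$locomotion_gain,
                            as.list(fac), cfg$pattern_degradation)
      truth_tuning[[j]] <- tibble::tibble(
        unit_id = unit_ids[j],
        direction = rep(directions, 4),
        locomotion = rep(c("still", "still", "running", "running"),
                         each = length(directions)),
        laser_on = rep(c(FALSE, TRUE, FALSE, TRUE), each = length(directions)),
        rate = c(curves$still_off, curves$still_on,
                 curves$running_off, curves$running_on))

      spikes <- vector("list", n_trials + 1L)
      base_rate_gap <- base * cfg$baseline_fraction
      for (i in seq_len(n_trials)) {
        key <- paste0(trial_state[i], if (trial_laser[i]) "_on" else "_off")
        lam <- curves[[key]][match(trial_dir[i], directions)]
        spikes[[i]] <- poisson_spikes(lam, onsets[i],
                                      onsets[i] + cfg$stim_duration)
      }
      # ongoing activity in the gray gaps (locomotion-gained while running)
      gap_starts <- c(0, onsets + cfg$stim_duration)
      gap_ends <- c(onsets, total_dur)
      gap_rates <- base_rate_gap *
        ifelse(c("still", trial_state) == "running", cfg$locomotion_gain, 1)
      gaps <- lapply(seq_along(gap_starts), function(i) {
        poisson_spikes(gap_rates[i], gap_starts[i], gap_ends[i])
      })
      spikes[[n_trials + 1L]] <- unlist(gaps)

      wf_par <- if (is_bs) {
        c(h = 0.20, ttp = 0.73, psd = 0.35)
      } else {
        c(h = 0.34, ttp = 0.32, psd = 0.14)
      }
      wf <- make_waveform(
        height = max(0.05, rnorm(1, wf_par[["h"]], 0.04)),
        ttp_ms = max(0.12, rnorm(1, wf_par[["ttp"]], 0.08)),
        peak_sd_ms = wf_par[["psd"]] * exp(rnorm(1, 0, 0.1)),
        rate = cfg$waveform_rate)

      units[[j]] <- unit(
        unit_id = unit_ids[j],
        spike_times = sort(unlist(spikes)),
        mean_waveform = wf, waveform_rate = cfg$waveform_rate,
        channel_index = ((j - 1L) %% max(1L, cfg$n_channels)) + 1L,
        sort_class = "SU")
    }

    lfp <- if (include_lfp) {
      build_lfp(cfg, total_dur, loco$state, cfg$speed_bin,
                laser_events, stim_events)
    } else {
      matrix(numeric(), 0, 0)
    }
    depths <- if (include_lfp) {
      100 + cfg$channel_spacing * (seq_len(cfg$n_channels) - 1)
    } else numeric()

    sess <- session(
      subject_id = sprintf("synthetic_%d", cfg$seed),
      region = "V1", opsin = "ChR2",
      lfp = lfp, lfp_rate = cfg$lfp_rate,
      channel_depths = depths,
      channel_shank = rep(1L, length(depths)),
      units = units, speed = speed,
      stimulus_events = stim_events, laser_events = laser_events,
      duration = total_dur)

    truth <- structure(list(
      units = tibble::tibble(unit_id = unit_ids, cell_class = cell_class,
                             pref_direction = pref),
      tuning = dplyr::bind_rows(truth_tuning),
      gamma = tibble::tibble(
        locomotion = rep(c("still", "running"), each = 2),
        laser_on = rep(c(FALSE, TRUE), 2),
        power = cfg$gamma_amp_still^2 *
          c(1, cfg$gamma_opto_factor,
            cfg$gamma_run_gain, cfg$gamma_run_gain * cfg$gamma_opto_factor)),
      config = cfg), class = "optovis_ground_truth")

    list(session = sess, truth = truth)
  })
}

#' Generate a gray-screen block with periodic laser pulses
#'
#' No visual stimulus is shown (uniform gray); the laser is driven for 4 s
#' every 20 s. The LFP gamma power switches with the pulses and with
#' locomotion exactly as in [generate_session()]; units fire at their
#' ongoing rates, scaled by the opto factor during pulses.
#'
#' @param cfg A [generator_config()].
#' @param block_duration Block length in seconds (default 200 s, i.e. 10
#'   pulses).
#' @param pulse_duration,pulse_period Laser pulse length and period, seconds.
#' @param include_lfp As in [generate_session()].
#' @return A list with `session` and `truth` as in [generate_session()].
#' @export
generate_gray_block <- function(cfg = generator_config(),
                                block_duration = 200,
                                pulse_duration = 4, pulse_period = 20,
                                include_lfp = TRUE) {
  stopifnot(inherits(cfg, "generator_config"))
  if (pulse_duration >= pulse_period || pulse_duration <= 0) {
    abort("need 0 < pulse_duration < pulse_period")
  }
  with_seed(derive_seed(cfg$seed, 2L), {
    n_pulses <- floor(block_duration / pulse_period)
    lead <- (pulse_period - pulse_duration) / 2
    onsets <- lead + pulse_period * (seq_len(n_pulses) - 1)
    laser_events <- tibble::tibble(onset = onsets, duration = pulse_duration)

    stim_events <- tibble::tibble(
      onset = 0, duration = block_duration, kind = "gray",
      direction = NA_real_, spatial_freq = NA_real_, temporal_freq = NA_real_)

    loco <- simulate_locomotion(ceiling(block_duration / cfg$speed_bin),
                                cfg$run_bout_rates)
    speed <- tibble::tibble(
      t = (seq_along(loco$v) - 1) * cfg$speed_bin, v = loco$v)

    n_units <- cfg$n_units_bs + cfg$n_units_ns
    cell_class <- c(rep("BS", cfg$n_units_bs), rep("NS", cfg$n_units_ns))
    unit_ids <- sprintf("u%02d_%s", seq_len(n_units), tolower(cell_class))
    units <- vector("list", n_units)
    # piecewise-constant ongoing rate over laser segments
    seg_bounds <- sort(unique(c(0, onsets, onsets + pulse_duration,
                                block_duration)))
    for (j in seq_len(n_units)) {
      is_bs <- cell_class[j] == "BS"
      base <- (if (is_bs) cfg$base_rate_bs else cfg$base_rate_ns) *
        cfg$baseline_fraction
      fac <- if (is_bs) cfg$opto_rate_factor_bs else cfg$opto_rate_factor_ns
      st <- lapply(seq_len(length(seg_bounds) - 1L), function(i) {
        a <- seg_bounds[i]; b <- seg_bounds[i + 1L]
        on <- any(onsets <= a + 1e-9 & a < onsets + pulse_duration - 1e-9)
        poisson_spikes(base * (if (on) fac[["still"]] else 1), a, b)
      })
      wf_par <- if (is_bs) c(h = 0.20, ttp = 0.73, psd = 0.35) else
        c(h = 0.34, ttp = 0.32, psd = 0.14)
      units[[j]] <- unit(
        unit_id = unit_ids[j], spike_times = sort(unlist(st)),
        mean_waveform = make_waveform(wf_par[["h"]], wf_par[["ttp"]],
                                      wf_par[["psd"]], cfg$waveform_rate),
        waveform_rate = cfg$waveform_rate,
        channel_index = ((j - 1L) %% max(1L, cfg$n_channels)) + 1L,
        sort_class = "SU")
    }

    lfp <- if (include_lfp) {
      build_lfp(cfg, block_duration, loco$state, cfg$speed_bin,
                laser_events, stim_events)
    } else matrix(numeric(), 0, 0)
    depths <- if (include_lfp) {
      100 + cfg$channel_spacing * (seq_len(cfg$n_channels) - 1)
    } else numeric()

    sess <- session(
      subject_id = sprintf("synthetic_gray_%d", cfg$seed),
      region = "V1", opsin = "ChR2",
      lfp = lfp, lfp_rate = cfg$lfp_rate,
      channel_depths = depths, channel_shank = rep(1L, length(depths)),
      units = units, speed = speed,
      stimulus_events = stim_events, laser_events = laser_events,
      duration = block_duration)

    truth <- structure(list(
      units = tibble::tibble(unit_id = unit_ids, cell_class = cell_class,
                             pref_direction = NA_real_),
      tuning = tibble::tibble(),
      gamma = tibble::tibble(
        locomotion = rep(c("still", "running"), each = 2),
        laser_on = rep(c(FALSE, TRUE), 2),
        power = cfg$gamma_amp_still^2 *
          c(1, cfg$gamma_opto_factor,
            cfg$gamma_run_gain, cfg$gamma_run_gain * cfg$gamma_opto_factor)),
      config = cfg), class = "optovis_ground_truth")

    list(session = sess, truth = truth)
  })
}

#' Generate a filtered-noise movie and linear-nonlinear model units
#'
#' Frames are spatially low-pass-filtered white noise (zero mean). Each
#' generated unit fires as an inhomogeneous Poisson process whose rate is a
#' rectified linear function of the inner product between the current frame
#' and a centre-surround (difference-of-Gaussians) kernel, so its
#' spike-triggered average converges to the kernel as spikes accumulate.
#'
#' @param cfg A [generator_config()] (supplies the seed).
#' @param n_frames Number of movie frames.
#' @param side Frame side length in pixels (frames are `side x side`).
#' @param frame_duration Seconds per frame.
#' @param n_units Number of LN units to simulate.
#' @param gain Rate modulation depth (Hz per unit filter output SD).
#' @param base_rate Mean firing rate, Hz.
#' @param cutoff Spatial low-pass Gaussian SD in pixels.
#'
#' @return A list with `movie` (frames x pixels matrix), `frame_duration`,
#'   `side`, `kernel` (pixel vector, one shared kernel), and `units` (list
#'   of [unit()]s whose spike times index into the movie timeline).
#' @export
generate_noise_movie <- function(cfg = generator_config(), n_frames = 3000,
                                 side = 12, frame_duration = 1 / 30,
                                 n_units = 2, gain = 8, base_rate = 10,
                                 cutoff = 1.5) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(derive_seed(cfg$seed, 3L), {
    npix <- side * side
    raw <- matrix(rnorm(n_frames * npix), nrow = n_frames)
    # spatial low-pass: Gaussian blur each frame via separable kernel
    g <- dnorm(seq(-3, 3), sd = cutoff / 2)
    g <- g / sum(g)
    blur1d <- function(m) {  # rows of m are signals
      k <- length(g)
      pad <- (k - 1) / 2
      mp <- cbind(m[, rep(1, pad), drop = FALSE], m,
                  m[, rep(ncol(m), pad), drop = FALSE])
      out <- matrix(0, nrow(m), ncol(m))
      for (i in seq_len(k)) {
        out <- out + g[i] * mp[, i:(i + ncol(m) - 1), drop = FALSE]
      }
      out
    }
    movie <- t(vapply(seq_len(n_frames), function(fi) {
      fr <- matrix(raw[fi, ], side, side)
      fr <- blur1d(fr)
      fr <- t(blur1d(t(fr)))
      as.numeric(fr)
    }, numeric(npix)))
    movie <- sweep(movie, 2, colMeans(movie))  # zero-mean pixels

    xy <- expand.grid(x = seq_len(side), y = seq_len(side))
    cx <- (side + 1) / 2
    r2 <- (xy$x - cx)^2 + (xy$y - cx)^2
    kernel <- exp(-r2 / (2 * 1.5^2)) - 0.55 * exp(-r2 / (2 * 3^2))
    kernel <- kernel / sqrt(sum(kernel^2))

    drive <- as.numeric(movie %*% kernel)
    drive <- drive / sd(drive)
    units <- lapply(seq_len(n_units), function(j) {
      lam <- pmax(0, base_rate + gain * drive)
      k <- rpois(n_frames, lam * frame_duration)
      st <- rep((seq_len(n_frames) - 0.5) * frame_duration, k)
      unit(unit_id = sprintf("ln%02d", j), spike_times = sort(st),
           mean_waveform = make_waveform(0.2, 0.73, 0.35, cfg$waveform_rate),
           waveform_rate = cfg$waveform_rate, sort_class = "unknown")
    })
    list(movie = movie, frame_duration = frame_duration, side = side,
         kernel = kernel, units = units)
  })
}
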