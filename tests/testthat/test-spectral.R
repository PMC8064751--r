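test_that("band-pass keeps in-band and rejects out-of-band components", {
  fs <- 2000
  t <- seq(1 / fs, 4, by = 1 / fs)
  in_band <- sin(2 * pi * 50 * t)
  y <- lfp_bandpass(in_band, fs)
  mid <- seq(fs, 3 * fs)  # avoid edge transients
  expect_lt(abs(sd(y[mid]) - sd(in_band[mid])) / sd(in_band[mid]), 0.05)

  out_band <- sin(2 * pi * 600 * t)
  y2 <- lfp_bandpass(out_band, fs)
  expect_lt(sd(y2[mid]) / sd(out_band[mid]), 0.1)

  dc <- rep(5, length(t))
  y3 <- lfp_bandpass(dc + in_band, fs)
  expect_lt(abs(mean(y3[mid])), 0.05)

  expect_error(lfp_bandpass(in_band, fs = 500), "Nyquist")
})

test_that("wavelet power peaks at the sinusoid frequency", {
  fs <- 500
  t <- seq(1 / fs, 10, by = 1 / fs)
  sp <- morlet_power(sin(2 * pi * 40 * t), fs)
  grid <- sp$freq
  expect_equal(sp$freq[which.max(sp$power)], grid[which.min(abs(grid - 40))])

  # zero signal -> all-zero power
  sp0 <- morlet_power(rep(0, length(t)), fs)
  expect_true(all(sp0$power == 0))

  # window must fit 3 cycles of the lowest frequency
  expect_error(morlet_power(sin(2 * pi * 40 * t), fs, window = c(0, 1)),
               "3 cycles")
})

test_that("a two-tone signal has local maxima at both tones", {
  fs <- 500
  t <- seq(1 / fs, 20, by = 1 / fs)
  x <- sin(2 * pi * 10 * t) + sin(2 * pi * 60 * t)
  sp <- morlet_power(x, fs)
  p <- sp$power
  loc_max <- which(diff(sign(diff(p))) == -2) + 1
  near <- function(f) any(abs(sp$freq[loc_max] - f) / f < 0.1)
  expect_true(near(10))
  expect_true(near(60))
})

test_that("wavelet total power agrees with the periodogram oracle", {
  set.seed(7)
  fs <- 500
  x <- rnorm(fs * 20)  # unit-variance white noise
  cfg <- spectral_config()
  sp <- morlet_power(x, fs, cfg = cfg)
  # integrate wavelet PSD over the grid span (trapezoid) and compare with
  # the periodogram power in the same band
  f <- sp$freq
  tot_wavelet <- sum(diff(f) * (head(sp$power, -1) + tail(sp$power, -1)) / 2)
  tot_oracle <- periodogram_band_power(x, fs, min(f), max(f))
  expect_lt(abs(tot_wavelet - tot_oracle) / tot_oracle, 0.2)
})

test_that("1/f adjustment flattens a power-law spectrum and guards reapplication", {
  fs <- 500
  t <- seq(1 / fs, 10, by = 1 / fs)
  sp <- morlet_power(sin(2 * pi * 40 * t), fs)
  synth <- sp
  synth$power <- synth$freq^(-2.5)
  adj <- adjust_one_over_f(synth, alpha = 2.5)
  expect_lt(max(adj$power) / min(adj$power), 1.1)
  expect_error(adjust_one_over_f(adj, 2.5), "twice")

  # alpha = 0 is the identity
  same <- adjust_one_over_f(synth, alpha = 0)
  expect_equal(same$power, synth$power)

  # direct evaluation at a single frequency
  one <- synth
  one$power <- as.numeric(synth$freq == synth$freq[1])
  adj1 <- adjust_one_over_f(one, 2.5)
  expect_equal(max(adj1$power), synth$freq[1]^2.5)

  # adjust then multiply back recovers the input to machine precision
  back <- adj
  back$power <- back$power * back$freq^(-2.5)
  expect_equal(back$power, synth$power, tolerance = 1e-12)
})

test_that("band power averages inclusively over grid frequencies", {
  spec <- tibble::tibble(channel = 1L,
                         freq = c(2, 4, 8, 20, 30, 40, 55, 80),
                         power = 1)
  spec <- optovis:::new_power_spectrum(spec, FALSE, 7, 1L)
  expect_equal(band_power(spec, "theta")$power, 1)
  expect_equal(band_power(spec, "gamma")$power, 1)

  # 30 Hz belongs to both edges it bounds; gamma includes it
  spec2 <- spec
  spec2$power <- as.numeric(spec2$freq == 40)
  expect_gt(band_power(spec2, "gamma")$power, 0)
  expect_equal(band_power(spec2, "theta")$power, 0)
  expect_equal(band_power(spec2, "beta")$power, 0)

  # arithmetic mean over in-band grid points
  spec3 <- tibble::tibble(channel = 1L, freq = seq(30, 80, by = 10),
                          power = seq(30, 80, by = 10))
  spec3 <- optovis:::new_power_spectrum(spec3, FALSE, 7, 1L)
  expect_equal(band_power(spec3, "gamma")$power, 55)

  expect_error(band_power(spec, c(300, 400)), "no grid frequency")
})

test_that("band power is linear and monotone in the spectrum", {
  set.seed(11)
  base <- tibble::tibble(channel = 1L,
                         freq = exp(seq(log(2), log(100), length.out = 30)),
                         power = runif(30))
  base <- optovis:::new_power_spectrum(base, FALSE, 7, 1L)
  bigger <- base
  bigger$power <- base$power + 0.5
  scaled <- base
  scaled$power <- 3 * base$power
  for (b in c("theta", "beta", "gamma")) {
    expect_gte(band_power(bigger, b)$power, band_power(base, b)$power)
    expect_equal(band_power(scaled, b)$power, 3 * band_power(base, b)$power)
  }
})

test_that("evoked minus ongoing subtracts matched spectra", {
  mk <- function(p) {
    s <- tibble::tibble(channel = 1L, freq = c(5, 20, 50), power = p)
    optovis:::new_power_spectrum(s, FALSE, 7, 1L)
  }
  same <- evoked_minus_ongoing(list(mk(c(1, 2, 3)), mk(c(3, 2, 1))),
                               list(mk(c(1, 2, 3)), mk(c(3, 2, 1))))
  expect_true(all(same$power_diff == 0))

  shifted <- evoked_minus_ongoing(list(mk(c(2, 3, 4))), list(mk(c(1, 2, 3))))
  expect_true(all(shifted$power_diff == 1))

  bad <- tibble::tibble(channel = 1L, freq = c(6, 21, 51), power = 1:3)
  bad <- optovis:::new_power_spectrum(bad, FALSE, 7, 1L)
  expect_error(evoked_minus_ongoing(list(mk(1:3)), list(bad)), "grids")
})

test_that("stimulus-evoked gamma shows up in the evoked-ongoing contrast", {
  cfg <- generator_config(seed = 41, n_repeats = 3, n_channels = 1,
                          stim_gamma_gain = 2)
  g <- generate_session(cfg, include_lfp = TRUE)
  s <- g$session
  ev <- s$stimulus_events[s$stimulus_events$kind == "grating", ]
  scfg <- spectral_config(freq_grid = exp(seq(log(4), log(90),
                                              length.out = 30)))
  take <- head(seq_len(nrow(ev)), 12)
  evoked <- lapply(take, function(i) {
    morlet_power(s$lfp, s$lfp_rate,
                 window = c(ev$onset[i], ev$onset[i] + 2), cfg = scfg)
  })
  ongoing <- lapply(take, function(i) {
    morlet_power(s$lfp, s$lfp_rate,
                 window = c(ev$onset[i] - 2, ev$onset[i]), cfg = scfg)
  })
  d <- evoked_minus_ongoing(evoked, ongoing)
  gamma_d <- mean(d$power_diff[d$freq >= 30 & d$freq <= 80])
  theta_d <- mean(d$power_diff[d$freq >= 4 & d$freq <= 8])
  expect_gt(gamma_d, 0)
  expect_lt(abs(theta_d), gamma_d / 2)
})

test_that("CSD is the negative second spatial difference", {
  # linear depth profile -> identically zero CSD
  depths <- seq(100, 400, by = 50)
  v_lin <- matrix(rep(depths * 0.01, 10), ncol = 10)
  csd <- compute_csd(v_lin, depth_spacing = 50)
  expect_equal(max(abs(csd)), 0)
  expect_equal(nrow(csd), length(depths) - 2)

  # Gaussian bump across depth: single extremum at the centre; the second
  # derivative is most negative at the peak, so -V''/h^2 is maximal there
  prof <- exp(-((seq_along(depths)) - 4)^2 / 2)
  v_g <- matrix(prof, ncol = 1)
  csd_g <- compute_csd(v_g, depth_spacing = 50)
  expect_equal(unname(which.max(csd_g[, 1])), 3)  # row 3 = channel 4
  # a negative-voltage bump (extracellular sink signature) flips the sign
  csd_n <- compute_csd(-v_g, depth_spacing = 50)
  expect_equal(unname(which.min(csd_n[, 1])), 3)

  # exactly one output channel from 3 inputs
  expect_equal(nrow(compute_csd(matrix(1:3, ncol = 1), 50)), 1)

  expect_error(compute_csd(v_lin, depths = c(100, 150, 220, 300, 350, 400,
                                             450)),
               "uniform")
})

test_that("laser reduces generated gamma band power when configured", {
  cfg <- generator_config(seed = 43, n_channels = 1)
  gb <- generate_gray_block(cfg, block_duration = 120)
  bp <- condition_band_power(gb$session, window_length = 4)
  still <- bp[bp$locomotion == "still", ]
  expect_lt(mean(still$power[still$laser_on]),
            mean(still$power[!still$laser_on]))
})
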