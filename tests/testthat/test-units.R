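test_that("waveform features recover template geometry", {
  rate <- 20000
  dt_ms <- 1000 / rate
  # triangular waveform with symmetric peak and trough
  t_ms <- seq(0, 3, by = dt_ms)
  tri <- pmax(0, 1 - abs(t_ms - 2) / 0.4) - pmax(0, 1 - abs(t_ms - 1) / 0.4)
  f <- waveform_features(tri, rate)
  expect_equal(f$peak_trough_height, 1.0, tolerance = 1e-6)
  expect_equal(f$trough_to_peak_ms, 1.0, tolerance = 0.01)

  # linear ramp after the trough: central difference is exact
  ramp <- c(seq(0, -1, length.out = 21), seq(-1, 2, length.out = 61)[-1])
  fr <- waveform_features(ramp, rate)
  true_slope <- (3 / 60) / dt_ms  # normalized amplitude per ms
  expect_equal(fr$post_trough_slope, true_slope, tolerance = 1e-6)

  # trough at the last sample is an error
  expect_error(waveform_features(seq(1, -1, length.out = 50), rate),
               "1 ms")
})

test_that("template features sit near the configured class centroids", {
  wf_bs <- optovis:::make_waveform(0.20, 0.73, 0.35, 20000)
  wf_ns <- optovis:::make_waveform(0.34, 0.32, 0.14, 20000)
  f_bs <- waveform_features(wf_bs, 20000)
  f_ns <- waveform_features(wf_ns, 20000)
  expect_lt(abs(f_bs$trough_to_peak_ms - 0.73), 0.05)
  expect_lt(abs(f_ns$trough_to_peak_ms - 0.32), 0.05)
  expect_equal(f_bs$peak_trough_height, 0.20, tolerance = 0.05)
  expect_equal(f_ns$peak_trough_height, 0.34, tolerance = 0.05)
  # slope sign structure: BS still rising at 0.5 ms, NS already falling
  expect_gt(f_bs$post_trough_slope, 0)
  expect_lt(f_ns$post_trough_slope, 0)
})

test_that("NS/BS classification follows the trough-to-peak rule", {
  feats <- tibble::tibble(
    unit_id = c("a", "b"),
    peak_trough_height = c(0.2, 0.34),
    trough_to_peak_ms = c(0.7, 0.3),
    post_trough_slope = c(0.01, -0.01))
  res <- classify_ns_bs(feats)
  expect_equal(res$labels$cell_class, c("BS", "NS"))

  # permutation equivariance: reordering units reorders labels
  res_rev <- classify_ns_bs(feats[2:1, ])
  expect_equal(res_rev$labels$cell_class, c("NS", "BS"))

  expect_error(classify_ns_bs(feats[c(1, 1), ]), "identical")
})

test_that("classification is invariant to affine rescaling of one feature", {
  g <- cached_session(seed = 51, n_repeats = 2)
  feats <- session_waveform_features(g$session)
  base <- classify_ns_bs(feats)$labels$cell_class
  scaled <- feats
  scaled$post_trough_slope <- 100 * scaled$post_trough_slope + 7
  expect_equal(classify_ns_bs(scaled)$labels$cell_class, base)
})

test_that("generated populations are classified by waveform at high accuracy", {
  g <- cached_session(seed = 52, n_repeats = 2)
  feats <- session_waveform_features(g$session)
  res <- classify_ns_bs(feats)
  joined <- dplyr::left_join(res$labels, g$truth$units, by = "unit_id")
  acc <- mean(joined$cell_class.x == joined$cell_class.y)
  expect_gte(acc, 0.95)
  # BS centroid has the larger trough-to-peak by construction
  expect_gt(res$centroids["BS", "trough_to_peak_ms"],
            res$centroids["NS", "trough_to_peak_ms"])
})

test_that("condition rates average counts over matching trials", {
  s <- tiny_session(spike_times_1 = c(0.6, 0.7, 0.9, 4.6, 4.7, 4.8, 4.9, 5.2))
  tr <- build_trials(s)
  # trial counts: 3 and 5 in 1 s windows -> 4 Hz overall
  expect_equal(condition_rate(tr, "u1"), 4)
  expect_equal(condition_rate(tr, "u2"), 0)
  expect_error(condition_rate(tr, "u1", laser_on = TRUE), "no trials")
  expect_error(condition_rate(tr, "nope"), "no such unit")
})

test_that("laser rate ratio handles identical rates and silent units", {
  s <- tiny_session(spike_times_1 = c(0.6, 4.6), laser_onsets = 4)
  tr <- build_trials(s)
  expect_equal(laser_rate_ratio(tr, "u1", "still"), 1.0)
  expect_warning(r <- laser_rate_ratio(tr, "u2", "still"), "zero")
  expect_true(is.na(r))

  # silent only in laser-on trials -> ratio 0
  s2 <- tiny_session(spike_times_1 = c(0.6), laser_onsets = 4)
  tr2 <- build_trials(s2)
  expect_equal(laser_rate_ratio(tr2, "u1", "still"), 0)
})

test_that("evoked/baseline ratio identifies the optimal direction", {
  # direction 90 evoked strongly; baseline spikes before each onset
  s <- tiny_session(
    spike_times_1 = c(3.8, 4.6, 4.7, 4.8, 4.9, 5.1, 5.3, 5.4),
    directions = c(0, 90), stim_onsets = c(0, 4))
  tr <- build_trials(s)
  r <- evoked_baseline_ratio(s, "u1", tr, pre_window = 0.5)
  expect_equal(r$optimal_direction, 90)
  expect_gt(r$ratio, 1)

  # evoked 10 Hz vs baseline 5 Hz -> ratio 2 (counts 10 in window, 2.5 in
  # 0.5 s pre-window): construct directly
  pre <- seq(3.55, 3.95, by = 0.2)          # 3 spikes in 0.5 s -> 6 Hz
  stim <- seq(4.51, 5.49, length.out = 12)  # 12 Hz evoked
  s3 <- tiny_session(spike_times_1 = c(pre, stim))
  tr3 <- build_trials(s3)
  r3 <- evoked_baseline_ratio(s3, "u1", tr3, pre_window = 0.5)
  expect_equal(r3$ratio, 2, tolerance = 1e-9)
})

test_that("a stimulus-independent unit has evoked/baseline ratio near 1", {
  # constant-rate Poisson unit: firing ignores the stimulus entirely, so the
  # ratio should sit at 1 up to sampling noise (plus a small upward
  # selection bias from picking the argmax direction)
  set.seed(55)
  n_trials <- 160
  onsets <- 2 + (seq_len(n_trials) - 1) * 4
  dirs <- rep(seq(0, 315, by = 45), length.out = n_trials)
  dur <- 2 + n_trials * 4
  rate <- 20
  k <- rpois(1, rate * dur)
  spikes <- sort(runif(k, 0, dur))
  s <- session(
    subject_id = "null", region = "V1", opsin = "eYFP",
    units = list(unit("u1", spikes)),
    speed = tibble::tibble(t = seq(0, dur - 0.1, by = 0.1),
                           v = rep(0, dur * 10)),
    stimulus_events = tibble::tibble(
      onset = onsets, duration = 2, kind = "grating", direction = dirs,
      spatial_freq = 0.04, temporal_freq = 1),
    duration = dur)
  tr <- build_trials(s)
  r <- evoked_baseline_ratio(s, "u1", tr, pre_window = 1)
  expect_equal(r$ratio, 1, tolerance = 0.2)
})

test_that("tuned units prefer their configured direction", {
  g <- cached_session(seed = 54, n_repeats = 20, pattern_degradation = 0,
                      tuning_concentration = 4)
  tr <- build_trials(g$session)
  sess <- g$session
  truth <- g$truth
  ids <- attr(tr, "unit_ids")[1:8]
  hits <- vapply(ids, function(id) {
    r <- evoked_baseline_ratio(sess, id, tr)
    tt <- truth$tuning[truth$tuning$unit_id == id &
                         !truth$tuning$laser_on &
                         truth$tuning$locomotion == "still", ]
    best_true <- tt$direction[which.max(tt$rate)]
    (r$ratio > 1) && (min(abs(c(r$optimal_direction - best_true,
                                r$optimal_direction - best_true + 360,
                                r$optimal_direction - best_true - 360))) <= 45)
  }, logical(1))
  expect_gte(mean(hits), 0.75)
})

test_that("coefficient of variation matches its definition and is scale-free", {
  expect_equal(coefficient_of_variation(c(2, 2, 2)), 0)
  expect_equal(coefficient_of_variation(c(1, 3)), sqrt(2) / 2)
  set.seed(3)
  r <- rpois(200, 9)
  expect_equal(coefficient_of_variation(r),
               coefficient_of_variation(3.7 * r))
  expect_warning(cv0 <- coefficient_of_variation(c(0, 0)), "zero mean")
  expect_true(is.na(cv0))
  expect_error(coefficient_of_variation(5), "2 trials")
})

test_that("Poisson CV approaches 1/sqrt(lambda)", {
  set.seed(8)
  lambda <- 16
  counts <- rpois(4000, lambda)
  expect_equal(coefficient_of_variation(counts), 1 / sqrt(lambda),
               tolerance = 0.05)
})

test_that("STA reproduces a locked frame and respects time reversal", {
  set.seed(13)
  movie <- matrix(rnorm(50 * 16), nrow = 50)
  fd <- 0.1
  # all spikes inside frame 7 -> STA is frame 7
  st <- c(0.61, 0.64, 0.69)
  sta <- spike_triggered_average(st, movie, fd)
  expect_equal(sta$frames[1, ], movie[7, ])

  # time-reversal symmetry
  span <- nrow(movie) * fd
  st_rev <- sort(span - st)
  movie_rev <- movie[nrow(movie):1, ]
  sta_rev <- spike_triggered_average(st_rev, movie_rev, fd)
  expect_equal(sta_rev$frames[1, ], sta$frames[1, ])

  expect_error(spike_triggered_average(numeric(), movie, fd), "no spikes")
})

test_that("SU/MU scoring is monotone in the threshold", {
  set.seed(14)
  movie <- matrix(rnorm(500 * 16), nrow = 500)
  sta_flat <- spike_triggered_average(runif(200, 0, 50), movie, 0.1)
  score <- sta_snr_score(sta_flat, pixel_sd = 1)
  expect_lt(score, 5)
  labels5 <- classify_su_mu(c(a = score, b = 50), threshold = 5)
  expect_equal(labels5$sort_class, c("MU", "SU"))
  labels_inf <- classify_su_mu(c(a = score, b = 50), threshold = Inf)
  expect_true(all(labels_inf$sort_class == "MU"))
})
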