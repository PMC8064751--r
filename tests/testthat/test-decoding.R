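test_that("orientation grouping folds directions mod 180", {
  expect_equal(group_orientations(c(0, 180)), c(1L, 1L))
  expect_equal(group_orientations(c(90, 270)), c(1L, 1L))
  dirs <- seq(0, 315, by = 45)
  cls <- group_orientations(dirs)
  expect_equal(length(unique(cls)), 4)
  expect_equal(cls[1:4], cls[5:8])
  expect_error(group_orientations(c(-10, 20)), "0, 360")
})

test_that("diagonal LDA fit matches hand-computed sufficient statistics", {
  # 2 classes, 2 units, 8 trials; hand-computed means and pooled variance
  X <- rbind(c(0, 2), c(1, 3), c(2, 2), c(1, 1),
             c(5, 7), c(6, 8), c(7, 7), c(6, 6))
  y <- rep(c("a", "b"), each = 4)
  m <- fit_diag_lda(X, y)
  expect_equal(m$class_means["a" == m$classes, ], c(1, 2),
               ignore_attr = TRUE)
  expect_equal(m$class_means["b" == m$classes, ], c(6, 7),
               ignore_attr = TRUE)
  # within-class SS: class a: (1,2) -> 2, 2; class b: 2, 2 => pooled (n-K=6)
  expect_equal(m$pooled_variances, c(4 / 6, 4 / 6), ignore_attr = TRUE)
  expect_equal(exp(m$class_log_priors), c(0.5, 0.5), ignore_attr = TRUE)

  expect_error(fit_diag_lda(X[c(1, 5, 6, 7), ], y[c(1, 5, 6, 7)]),
               "fewer than 2")
})

test_that("zero-variance features are floored, not divided by zero", {
  X <- cbind(c(0, 0, 5, 5), c(3, 3, 3, 3))  # second unit constant
  y <- c("a", "a", "b", "b")
  m <- fit_diag_lda(X, y)
  expect_true(all(is.finite(1 / m$pooled_variances)))
  p <- predict(m, c(0, 3))
  expect_equal(p, "a")
})

test_that("identical class data falls back to the prior tie-break", {
  X <- rbind(c(1, 1), c(2, 2), c(1, 1), c(2, 2))
  y <- c("a", "a", "b", "b")
  m <- fit_diag_lda(X, y)
  # equal means, equal priors: tie -> lowest class index
  expect_equal(predict(m, c(1.5, 1.5)), "a")
})

test_that("predict matches nearest-mean intuition and the tie rule", {
  m2 <- fit_diag_lda(matrix(c(0, 0.5, 10, 9.5)), c(1, 1, 2, 2))
  expect_equal(predict(m2, 2), 1)
  expect_equal(predict(m2, 9), 2)
  # exactly equidistant from both means with equal priors -> lower index
  expect_equal(predict(m2, mean(c(0.25, 9.75))), 1)
  expect_error(predict(m2, c(1, 2)), "expects")
})

test_that("predict agrees with the brute-force diagonal-Gaussian oracle", {
  set.seed(201)
  for (i in 1:25) {
    K <- sample(2:5, 1)
    p <- sample(1:4, 1)
    n_per <- 8
    means_true <- matrix(rnorm(K * p, sd = 3), K, p)
    X <- do.call(rbind, lapply(seq_len(K), function(ci) {
      sweep(matrix(rnorm(n_per * p), n_per, p), 2, means_true[ci, ], "+")
    }))
    y <- rep(seq_len(K), each = n_per)
    m <- fit_diag_lda(X, y)
    Xtest <- matrix(rnorm(40 * p, sd = 4), 40, p)
    got <- predict(m, Xtest)
    oracle <- apply(Xtest, 1, diag_gauss_oracle,
                    means = m$class_means, vars = m$pooled_variances,
                    priors = exp(m$class_log_priors))
    expect_equal(got, m$classes[oracle])
  }
})

test_that("LOOXV reaches 1 on separated classes and errors when degenerate", {
  X <- rbind(matrix(rpois(40, 2), 20), matrix(rpois(40, 30), 20))
  y <- rep(c(1, 2), each = 20)
  res <- looxv_accuracy(X, y)
  expect_equal(res$accuracy, 1.0)
  expect_equal(nrow(res$predictions), 40)
  expect_equal(res$accuracy, mean(res$predictions$correct))

  expect_error(looxv_accuracy(rbind(1, 2), c(1, 2)), "fewer than 2")
})

test_that("LOOXV is at chance for label-independent counts", {
  set.seed(202)
  for (K in c(2, 4)) {
    n <- 240
    X <- matrix(rpois(n * 8, 5), n, 8)
    y <- rep(seq_len(K), length.out = n)
    res <- looxv_accuracy(X, y)
    # binomial 99% envelope around 1/K
    se <- sqrt((1 / K) * (1 - 1 / K) / n)
    expect_lt(abs(res$accuracy - 1 / K), 3 * se + 0.02)
  }
})

test_that("LOOXV equals an explicit per-trial refit", {
  set.seed(203)
  X <- matrix(rpois(30 * 3, 4), 30, 3)
  X[16:30, ] <- X[16:30, ] + 3
  y <- rep(c(1, 2), each = 15)
  fast <- looxv_accuracy(X, y)
  # oracle: literal leave-one-out refit with the same n-1-K variance pooling
  slow <- vapply(seq_len(nrow(X)), function(i) {
    Xi <- X[-i, , drop = FALSE]; yi <- y[-i]
    classes <- sort(unique(yi))
    mu <- t(vapply(classes, function(c) colMeans(Xi[yi == c, , drop = FALSE]),
                   numeric(ncol(Xi))))
    W <- numeric(ncol(Xi))
    for (c in classes) {
      Zc <- Xi[yi == c, , drop = FALSE]
      W <- W + colSums(sweep(Zc, 2, colMeans(Zc))^2)
    }
    v <- W / (nrow(Xi) - length(classes))
    mp <- mean(W / (nrow(X) - length(classes)))
    v <- pmax(v, if (mp > 0) 1e-6 * mp else 1e-9)
    pri <- vapply(classes, function(c) mean(yi == c), numeric(1))
    sc <- vapply(seq_along(classes), function(ci) {
      log(pri[ci]) - 0.5 * sum((X[i, ] - mu[ci, ])^2 / v)
    }, numeric(1))
    classes[which.max(sc)]
  }, numeric(1))
  expect_equal(fast$predictions$predicted, slow)
})

test_that("adding a constant uninformative unit leaves predictions unchanged", {
  set.seed(204)
  X <- matrix(rpois(60 * 4, 6), 60, 4)
  X[31:60, 1] <- X[31:60, 1] + 4
  y <- rep(c(1, 2), each = 30)
  base <- looxv_accuracy(X, y)
  # a unit with identical counts everywhere contributes a constant term
  aug <- looxv_accuracy(cbind(X, 3L), y)
  expect_equal(base$predictions$predicted, aug$predictions$predicted)
})

test_that("subsampled accuracy distribution behaves at the edges", {
  set.seed(205)
  X <- matrix(rpois(80 * 5, 4), 80, 5)
  X[41:80, ] <- X[41:80, ] + 2
  y <- rep(c(1, 2), each = 40)
  full <- looxv_accuracy(X, y)$accuracy
  d1 <- subsampled_error_distribution(X, y, fraction = 1, n_reps = 5,
                                      seed = 11)
  expect_true(all(d1$accuracy == full))
  d2a <- subsampled_error_distribution(X, y, fraction = 0.5, n_reps = 10,
                                       seed = 12)
  d2b <- subsampled_error_distribution(X, y, fraction = 0.5, n_reps = 10,
                                       seed = 12)
  expect_identical(d2a, d2b)  # seeded reproducibility
  # subsample mean within 2 SD of the full-data accuracy
  expect_lt(abs(mean(d2a$accuracy) - full),
            2 * max(sd(d2a$accuracy), 0.05))
  expect_error(subsampled_error_distribution(X, y, fraction = 0.02), "fewer")
})

test_that("count-matched decoding pools counts and respects determinism", {
  g <- cached_session(seed = 71, n_repeats = 10, pattern_degradation = 0.8)
  tr <- build_trials(g$session)
  cm1 <- count_matched_decoding(tr, n_neuron_grid = c(4, 28), n_combos = 5,
                                n_boot = 200, seed = 3)
  cm2 <- count_matched_decoding(tr, n_neuron_grid = c(4, 28), n_combos = 5,
                                n_boot = 200, seed = 3)
  expect_identical(as.data.frame(cm1), as.data.frame(cm2))
  expect_true(all(cm1$accuracy >= 0 & cm1$accuracy <= 1, na.rm = TRUE))
  expect_true(all(diff(cm1$bin_lo[cm1$laser_on]) > 0))
  # populated bins carry a bootstrap SE
  pop <- cm1[cm1$n_samples > 0, ]
  expect_true(all(is.finite(pop$boot_se)))
  expect_error(count_matched_decoding(tr[!tr$laser_on, ]), "both laser")
})

test_that("full-population subset counts equal trial row sums", {
  g <- cached_session(seed = 72, n_repeats = 5)
  tr <- build_trials(g$session)
  n_units <- length(attr(tr, "unit_ids"))
  cm <- count_matched_decoding(tr, n_neuron_grid = n_units, n_combos = 1,
                               n_boot = 100, seed = 4,
                               count_bins = c(-0.5, 1e9))
  off <- tr[!tr$laser_on, ]
  on <- tr[tr$laser_on, ]
  expect_equal(cm$n_samples[!cm$laser_on], nrow(off))
  expect_equal(cm$n_samples[cm$laser_on], nrow(on))
})

test_that("decoding accuracy rises with tuning concentration", {
  accs <- vapply(c(0, 1, 4), function(k) {
    acc_seeds <- vapply(c(81, 82, 83), function(sd) {
      g <- cached_session(seed = sd, n_repeats = 10,
                          pattern_degradation = 0,
                          tuning_concentration = k)
      tr <- build_trials(g$session)
      sub <- tr[!tr$laser_on, ]
      looxv_accuracy(count_matrix(sub),
                     group_orientations(sub$direction))$accuracy
    }, numeric(1))
    mean(acc_seeds)
  }, numeric(1))
  expect_true(all(diff(accs) > 0))
})

test_that("tidy and glance expose decoder internals", {
  X <- rbind(matrix(rpois(20, 2), 10), matrix(rpois(20, 9), 10))
  y <- rep(c(1, 2), each = 10)
  m <- fit_diag_lda(X, y)
  td <- tidy(m)
  expect_equal(nrow(td), 2 * 2)
  gl <- glance(m)
  expect_equal(gl$n_classes, 2)
  res <- looxv_accuracy(X, y)
  expect_equal(nrow(tidy(res)), 20)
  expect_equal(glance(res)$accuracy, res$accuracy)
})
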