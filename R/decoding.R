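#' Group grating directions into orientation classes
#'
#' Gratings moving 180 degrees apart share an orientation; this maps
#' direction (degrees in [0, 360)) to `direction mod 180`, relabelled as
#' consecutive integers in ascending order of orientation.
#'
#' @param directions Numeric degrees in [0, 360).
#' @return Integer class labels (1-based).
#' @examples
#' group_orientations(c(0, 90, 180, 270))  # 1 2 1 2
#' @export
group_orientations <- function(directions) {
  if (any(directions < 0 | directions >= 360, na.rm = TRUE)) {
    abort("directions must lie in [0, 360)")
  }
  ori <- directions %% 180
  as.integer(factor(ori, levels = sort(unique(ori))))
}

#' Fit a diagonal-covariance linear discriminant model
#'
#' Gaussian class-conditional classifier assuming independence between
#' neurons (diagonal covariance shared across classes): class means are
#' per-class feature means, the per-feature variance is pooled within-class
#' (n - K denominator) and floored to avoid degenerate likelihoods for
#' silent units, and priors are empirical class frequencies unless equal
#' priors are requested.
#'
#' @param X Trials x units numeric count matrix.
#' @param y Class labels, one per trial; every class needs >= 2 trials.
#' @param variance_floor Minimum per-feature variance. Default:
#'   `1e-6 * mean(pooled variance)`, or `1e-9` if all variances are zero.
#' @param equal_priors Use uniform class priors (default: empirical).
#' @return An object of class `"diag_lda"`.
#' @export
fit_diag_lda <- function(X, y, variance_floor = NULL, equal_priors = FALSE) {
  X <- as.matrix(X)
  classes <- sort(unique(y))
  K <- length(classes)
  if (K < 2) abort("need at least 2 classes")
  nk <- vapply(classes, function(c) sum(y == c), numeric(1))
  if (any(nk < 2)) {
    abort(sprintf("class %s has fewer than 2 trials",
                  classes[which(nk < 2)[1]]))
  }
  n <- nrow(X)
  means <- do.call(rbind, lapply(classes, function(c) {
    colMeans(X[y == c, , drop = FALSE])
  }))
  W <- numeric(ncol(X))
  for (ci in seq_len(K)) {
    Xi <- X[y == classes[ci], , drop = FALSE]
    W <- W + colSums(sweep(Xi, 2, means[ci, ])^2)
  }
  pooled <- W / (n - K)
  if (is.null(variance_floor)) {
    mp <- mean(pooled)
    variance_floor <- if (mp > 0) 1e-6 * mp else 1e-9
  }
  pooled <- pmax(pooled, variance_floor)
  priors <- if (equal_priors) rep(1 / K, K) else nk / n
  structure(list(classes = classes, class_means = means,
                 pooled_variances = pooled,
                 class_log_priors = log(priors),
                 variance_floor = variance_floor,
                 n_trials = n),
            class = "diag_lda")
}

#' @export
print.diag_lda <- function(x, ...) {
  cat(sprintf("<diag_lda> %d classes, %d units, fit on %d trials\n",
              length(x$classes), ncol(x$class_means), x$n_trials))
  invisible(x)
}

#' @export
tidy.diag_lda <- function(x, ...) {
  tibble::tibble(
    class = rep(x$classes, ncol(x$class_means)),
    unit = rep(colnames(x$class_means) %||%
                 as.character(seq_len(ncol(x$class_means))),
               each = length(x$classes)),
    mean = as.numeric(x$class_means),
    variance = rep(x$pooled_variances, each = length(x$classes)))
}

#' @export
glance.diag_lda <- function(x, ...) {
  tibble::tibble(n_classes = length(x$classes),
                 n_units = ncol(x$class_means),
                 n_trials = x$n_trials,
                 variance_floor = x$variance_floor)
}

diag_lda_scores <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(model$class_means)) {
    abort(sprintf("x has %d units but the model expects %d",
                  ncol(X), ncol(model$class_means)))
  }
  K <- length(model$classes)
  iv <- 1 / model$pooled_variances
  sc <- matrix(0, nrow(X), K)
  for (ci in seq_len(K)) {
    d <- sweep(X, 2, model$class_means[ci, ])
    sc[, ci] <- model$class_log_priors[ci] - 0.5 * (d^2 %*% iv)
  }
  sc
}

#' Predict stimulus classes from unit counts
#'
#' Argmax over classes of `log prior - 0.5 * sum((x - mean)^2 / var)`;
#' score ties resolve to the lowest class index.
#'
#' @param object A fitted [fit_diag_lda()] model.
#' @param newdata Numeric vector (one trial) or trials x units matrix.
#' @param ... Unused.
#' @return Predicted class labels.
#' @export
predict.diag_lda <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1)
  sc <- diag_lda_scores(object, newdata)
  object$classes[apply(sc, 1, which.max)]  # which.max: first (lowest) index
}

#' Leave-one-out cross-validated decoding accuracy
#'
#' For each trial, a diagonal LDA model is fitted on every other trial
#' (leave-one-out) and used to predict the held-out trial; accuracy is the
#' proportion of correct predictions. Deterministic. The held-out fits use
#' fast mean/variance downdates of the full-data sufficient statistics, with
#' an `n - 1 - K` pooled-variance denominator.
#'
#' @param X Trials x units count matrix.
#' @param y Class labels (>= 2 trials per class).
#' @param equal_priors Use uniform priors in the held-out fits.
#' @return A list of class `"decoding_result"`: `accuracy`, `predictions`
#'   tibble (`trial`, `truth`, `predicted`, `correct`), `n_trials`,
#'   `classes`.
#' @export
looxv_accuracy <- function(X, y, equal_priors = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  classes <- sort(unique(y))
  K <- length(classes)
  if (K < 2) abort("need at least 2 classes")
  yk <- match(y, classes)
  nk <- tabulate(yk, K)
  if (any(nk < 2)) {
    abort(sprintf("class %s has fewer than 2 trials",
                  classes[which(nk < 2)[1]]))
  }
  if (n - 1 - K <= 0) abort("too few trials for held-out pooled variance")

  p <- ncol(X)
  S <- matrix(0, K, p)   # class feature sums
  Q <- matrix(0, K, p)   # class feature sums of squares
  for (ci in seq_len(K)) {
    Xi <- X[yk == ci, , drop = FALSE]
    S[ci, ] <- colSums(Xi)
    Q[ci, ] <- colSums(Xi^2)
  }
  W_full <- colSums(Q - S^2 / nk)

  mp <- mean(W_full / (n - K))
  floor_v <- if (mp > 0) 1e-6 * mp else 1e-9

  pred <- integer(n)
  for (i in seq_len(n)) {
    k <- yk[i]
    x <- X[i, ]
    nk_i <- nk
    nk_i[k] <- nk[k] - 1L
    # class-k mean and within-class SS after removing trial i
    mu <- S / nk
    mu[k, ] <- (S[k, ] - x) / nk_i[k]
    W <- W_full - (Q[k, ] - S[k, ]^2 / nk[k]) +
      (Q[k, ] - x^2 - (S[k, ] - x)^2 / max(1L, nk_i[k]))
    v <- pmax(W / (n - 1 - K), floor_v)
    lp <- if (equal_priors) rep(-log(K), K) else log(nk_i / (n - 1))
    d2 <- sweep(mu, 2, x)^2
    sc <- lp - 0.5 * as.numeric(d2 %*% (1 / v))
    pred[i] <- which.max(sc)
  }
  predictions <- tibble::tibble(trial = seq_len(n), truth = classes[yk],
                                predicted = classes[pred],
                                correct = pred == yk)
  structure(list(accuracy = mean(predictions$correct),
                 predictions = predictions, n_trials = n, classes = classes),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> accuracy %.3f over %d trials, %d classes\n",
              x$accuracy, x$n_trials, length(x$classes)))
  invisible(x)
}

#' @export
tidy.decoding_result <- function(x, ...) x$predictions

#' @export
glance.decoding_result <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, n_trials = x$n_trials,
                 n_classes = length(x$classes))
}

#' Distribution of decoding accuracies over trial subsamples
#'
#' Draws stratified trial subsamples (without replacement, the same fraction
#' from every class), runs [looxv_accuracy()] on each, and returns the
#' resulting accuracy distribution. Seeded and reproducible.
#'
#' @param X,y As in [looxv_accuracy()].
#' @param fraction Fraction of each class's trials to keep; every class must
#'   retain >= 2 trials.
#' @param n_reps Number of subsamples (default 50).
#' @param seed Integer seed.
#' @param equal_priors Passed through.
#' @return Tibble with columns `rep` and `accuracy`.
#' @export
subsampled_error_distribution <- function(X, y, fraction, n_reps = 50,
                                          seed = 1, equal_priors = FALSE) {
  X <- as.matrix(X)
  if (fraction <= 0 || fraction > 1) abort("fraction must be in (0, 1]")
  classes <- sort(unique(y))
  keep_n <- vapply(classes, function(c) round(fraction * sum(y == c)),
                   numeric(1))
  if (any(keep_n < 2)) {
    abort("subsample would leave a class with fewer than 2 trials")
  }
  with_seed(seed, {
    purrr::map_dfr(seq_len(n_reps), function(r) {
      idx <- unlist(lapply(seq_along(classes), function(ci) {
        pool <- which(y == classes[ci])
        sort(sample(pool, keep_n[ci]))
      }))
      tibble::tibble(
        rep = r,
        accuracy = looxv_accuracy(X[idx, , drop = FALSE], y[idx],
                                  equal_priors = equal_priors)$accuracy)
    })
  })
}

# Greedy left-to-right merge of integer-width count bins until every bin
# holds at least min_n pooled samples.
merge_count_bins <- function(counts, min_n = 20) {
  lo <- floor(min(counts))
  hi <- floor(max(counts))
  edges <- lo:(hi + 1L)
  repeat {
    idx <- findInterval(counts, edges - 0.5, rightmost.closed = TRUE)
    h <- tabulate(idx, length(edges) - 1L)
    small <- which(h < min_n)
    if (!length(small) || length(edges) <= 2) break
    j <- small[1]
    drop <- if (j == length(h)) j else j + 1L  # merge into the next bin
    edges <- edges[-drop]
  }
  edges - 0.5
}

#' Decoding accuracy at matched population spike counts
#'
#' Separates the rate and pattern contributions to a decoding deficit: for
#' each neuron-subset size in `n_neuron_grid` and each of `n_combos` sampled
#' subsets, trials within each laser condition are decoded by LOOXV and each
#' trial contributes a (population spike count, correct?) pair, where the
#' population count is the summed counts over the subset. Pairs are pooled
#' over subsets and binned by population count, so accuracies in the same
#' count bin compare laser-on and laser-off at equal firing levels - small
#' subsets supply the low-count bins for the laser-off condition and large
#' subsets the high-count bins for laser-on. Per bin and condition the
#' proportion correct and a bootstrap SE (1000 resamples) are reported.
#'
#' @param trials A trial table with both laser conditions.
#' @param class_map Direction-to-class map (default [group_orientations()]).
#' @param n_neuron_grid Subset sizes; default 4 log-spaced sizes from 1 to
#'   the full population.
#' @param n_combos Subsets sampled per size (default 100).
#' @param replace Sample neurons with replacement (default `FALSE`: a
#'   physical neuron cannot appear twice; set `TRUE` for the
#'   with-replacement variant).
#' @param locomotion Optional restriction to one locomotion state.
#' @param count_bins Numeric break points for population-count bins;
#'   default integer-width bins merged until each holds >= `min_bin_samples`
#'   pooled samples.
#' @param min_bin_samples Minimum pooled samples per auto-generated bin.
#' @param n_boot Bootstrap resamples for the per-bin SE.
#' @param seed Integer seed.
#' @param equal_priors Passed to the decoder.
#' @return A tibble of class `"count_matched_curve"`: `laser_on`, `bin_lo`,
#'   `bin_hi`, `bin_mid`, `n_samples`, `accuracy`, `boot_se`. Empty
#'   condition-bins appear with `n_samples = 0` and `NA` accuracy.
#' @export
count_matched_decoding <- function(trials, class_map = group_orientations,
                                   n_neuron_grid = NULL, n_combos = 100,
                                   replace = FALSE, locomotion = NULL,
                                   count_bins = NULL, min_bin_samples = 20,
                                   n_boot = 1000, seed = 1,
                                   equal_priors = FALSE) {
  if (!is.null(locomotion)) {
    trials <- trials[trials$locomotion == locomotion, , drop = FALSE]
  }
  if (length(unique(trials$laser_on)) < 2) {
    abort("trial table must contain both laser conditions")
  }
  ids <- attr(trials, "unit_ids")
  n_units <- length(ids)
  n_neuron_grid <- n_neuron_grid %||%
    unique(pmax(1, round(exp(seq(log(1), log(n_units), length.out = 4)))))

  cond_data <- lapply(c(FALSE, TRUE), function(on) {
    sub <- trials[trials$laser_on == on, , drop = FALSE]
    list(X = count_matrix(sub, ids), y = class_map(sub$direction))
  })

  with_seed(seed, {
    pairs <- purrr::map_dfr(n_neuron_grid, function(nn) {
      purrr::map_dfr(seq_len(n_combos), function(cb) {
        subset <- sample.int(n_units, nn, replace = replace)
        purrr::map_dfr(1:2, function(ci) {
          X <- cond_data[[ci]]$X[, subset, drop = FALSE]
          res <- looxv_accuracy(X, cond_data[[ci]]$y,
                                equal_priors = equal_priors)
          tibble::tibble(laser_on = ci == 2,
                         pop_count = rowSums(X),
                         correct = res$predictions$correct)
        })
      })
    })

    breaks <- count_bins %||% merge_count_bins(pairs$pop_count,
                                               min_bin_samples)
    bin_of <- function(x) findInterval(x, breaks, rightmost.closed = TRUE)
    pairs$bin <- bin_of(pairs$pop_count)

    grid <- tidyr::expand_grid(laser_on = c(FALSE, TRUE),
                               bin = seq_len(length(breaks) - 1))
    out <- purrr::pmap_dfr(grid, function(laser_on, bin) {
      sel <- pairs$laser_on == laser_on & pairs$bin == bin
      ns <- sum(sel)
      if (ns == 0) {
        acc <- NA_real_; se <- NA_real_
      } else {
        acc <- mean(pairs$correct[sel])
        se <- sd(rbinom(n_boot, ns, acc) / ns)
      }
      tibble::tibble(laser_on = laser_on,
                     bin_lo = breaks[bin], bin_hi = breaks[bin + 1],
                     bin_mid = (breaks[bin] + breaks[bin + 1]) / 2,
                     n_samples = ns, accuracy = acc, boot_se = se)
    })
    class(out) <- c("count_matched_curve", class(out))
    out
  })
}
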