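#' Two-sided rank tests
#'
#' Thin wrapper over [stats::wilcox.test()]: Wilcoxon rank-sum for unpaired
#' samples, signed-rank for paired samples (zero differences discarded per
#' the standard zero-discard rule). Exact p-values for small samples without
#' ties, normal approximation with tie correction otherwise.
#'
#' @param x,y Numeric samples (`length(x) == length(y)` when paired).
#' @param paired Paired test? Default `FALSE`.
#' @return A one-row tibble with `statistic`, `p_value`, `method`.
#' @export
rank_tests <- function(x, y, paired = FALSE) {
  if (length(x) < 2 || length(y) < 2) abort("need n >= 2 per sample")
  if (paired && length(x) != length(y)) {
    abort("paired test needs equal lengths")
  }
  if (paired && all(x == y)) {
    # all differences zero: no evidence against the null
    return(tibble::tibble(statistic = NA_real_, p_value = 1,
                          method = "Wilcoxon signed-rank"))
  }
  res <- suppressWarnings(
    stats::wilcox.test(x, y, paired = paired, exact = NULL, correct = TRUE))
  tibble::tibble(statistic = unname(res$statistic), p_value = res$p.value,
                 method = if (paired) "Wilcoxon signed-rank" else
                   "Wilcoxon rank-sum")
}

#' Spearman correlations with Bonferroni correction
#'
#' Spearman's rho for each (x, y) dataset with
#' `p_adjusted = min(1, m * p_raw)`, where `m` defaults to the number of
#' tests performed. Constant inputs have undefined rho and are flagged.
#'
#' @param pairs List of lists/tibbles each with elements `x` and `y`
#'   (n >= 3).
#' @param m Number of tests for the correction (default `length(pairs)`).
#' @return Tibble with `test`, `rho`, `p_raw`, `p_adjusted`, `degenerate`.
#' @export
spearman_bonferroni <- function(pairs, m = length(pairs)) {
  purrr::imap_dfr(pairs, function(d, i) {
    x <- d$x; y <- d$y
    if (length(x) < 3 || length(x) != length(y)) {
      abort("each dataset needs n >= 3 with equal lengths")
    }
    if (sd(x) == 0 || sd(y) == 0) {
      warn(sprintf("dataset %s: constant input, rho undefined", i))
      return(tibble::tibble(test = as.character(i), rho = NA_real_,
                            p_raw = NA_real_, p_adjusted = NA_real_,
                            degenerate = TRUE))
    }
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    tibble::tibble(test = as.character(i), rho = unname(ct$estimate),
                   p_raw = ct$p.value,
                   p_adjusted = min(1, m * ct$p.value),
                   degenerate = FALSE)
  })
}

#' Hierarchical (subject-stratified) permutation test
#'
#' Tests a condition effect on measurements nested within subjects without
#' pseudo-replication: the test statistic is the difference of the averages
#' of per-subject means (each subject weighted equally, however many
#' observations it contributes), and the null distribution is built by
#' permuting condition labels within subject (paired design: every subject
#' appears in both conditions) or by permuting subject-to-condition
#' assignments (unpaired design: disjoint subject sets). The p-value uses
#' the add-one rule `p = (1 + #{|perm| >= |obs|}) / (1 + n_perm)` and is
#' two-sided.
#'
#' A summary-statistic cross-check (Welch t-test on the subject means) is
#' included in the output.
#'
#' @param a,b Tibbles/data frames with columns `value` and `subject_id`.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return A list of class `"hier_perm_test"`: `p_value`,
#'   `observed_difference` (mean_a - mean_b on subject means), `paired`,
#'   `subject_means` tibble, `t_test_p` cross-check, `n_perm`.
#' @export
hierarchical_permutation_test <- function(a, b, n_perm = 10000, seed = 1) {
  a <- tibble::as_tibble(a); b <- tibble::as_tibble(b)
  for (d in list(a, b)) {
    if (!all(c("value", "subject_id") %in% names(d))) {
      abort("inputs need columns value and subject_id")
    }
  }
  subj_a <- unique(a$subject_id)
  subj_b <- unique(b$subject_id)
  paired <- setequal(subj_a, subj_b)
  all_subj <- union(subj_a, subj_b)
  if (length(all_subj) < 2 || (!paired && (length(subj_a) < 1 ||
                                           length(subj_b) < 1))) {
    abort("need at least 2 subjects; use within-subject tests otherwise")
  }
  if (!paired && length(intersect(subj_a, subj_b)) > 0) {
    abort("subject sets must be identical (paired) or disjoint (unpaired)")
  }
  if (paired && length(subj_a) < 2) {
    abort("paired design needs at least 2 subjects; use within-subject tests")
  }

  sm <- function(d) tapply(d$value, d$subject_id, mean)
  stat_paired <- function(a, b) {
    ma <- sm(a); mb <- sm(b)
    mean(ma) - mean(mb[names(ma)])
  }
  obs <- if (paired) stat_paired(a, b) else mean(sm(a)) - mean(sm(b))

  perm_stats <- with_seed(seed, {
    if (paired) {
      # pool each subject's observations, re-split into two groups of the
      # original sizes
      pooled <- lapply(subj_a, function(s) {
        va <- a$value[a$subject_id == s]
        vb <- b$value[b$subject_id == s]
        list(v = c(va, vb), na = length(va))
      })
      vapply(seq_len(n_perm), function(i) {
        ms <- vapply(pooled, function(p) {
          idx <- sample.int(length(p$v), p$na)
          c(mean(p$v[idx]), mean(p$v[-idx]))
        }, numeric(2))
        mean(ms[1, ]) - mean(ms[2, ])
      }, numeric(1))
    } else {
      means <- c(sm(a), sm(b))
      na <- length(subj_a)
      vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(length(means), na)
        mean(means[idx]) - mean(means[-idx])
      }, numeric(1))
    }
  })
  p <- (1 + sum(abs(perm_stats) >= abs(obs) - 1e-12)) / (1 + n_perm)

  ma <- sm(a); mb <- sm(b)
  tt <- tryCatch(
    stats::t.test(ma, mb[if (paired) names(ma) else names(mb)],
                  paired = paired)$p.value,
    error = function(e) NA_real_)
  subject_means <- dplyr::bind_rows(
    tibble::tibble(condition = "a", subject_id = names(ma),
                   mean_value = as.numeric(ma)),
    tibble::tibble(condition = "b", subject_id = names(mb),
                   mean_value = as.numeric(mb)))
  structure(list(p_value = p, observed_difference = obs, paired = paired,
                 subject_means = subject_means, t_test_p = tt,
                 n_perm = n_perm),
            class = "hier_perm_test")
}

#' @export
print.hier_perm_test <- function(x, ...) {
  cat(sprintf(
    "<hier_perm_test> %s design: observed diff %.4g, p = %.4g (%d perms)\n",
    if (x$paired) "paired" else "unpaired", x$observed_difference,
    x$p_value, x$n_perm))
  invisible(x)
}

#' @export
glance.hier_perm_test <- function(x, ...) {
  tibble::tibble(p_value = x$p_value,
                 observed_difference = x$observed_difference,
                 paired = x$paired, t_test_p = x$t_test_p,
                 n_perm = x$n_perm)
}
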