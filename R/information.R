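#' Shannon entropy of a probability vector
#'
#' `H = -sum p log2 p`, with `0 * log 0 = 0`. Probabilities must be
#' non-negative and sum to 1 (tolerance 1e-9).
#'
#' @param p Numeric probability vector.
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(p) {
  if (any(p < 0)) abort("probabilities must be >= 0")
  if (abs(sum(p) - 1) > 1e-9) abort("probabilities must sum to 1")
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Joint response-by-stimulus count table
#'
#' Contingency counts of response symbols (raw spike counts, optionally
#' capped so the tail pools into one symbol) against stimulus classes.
#'
#' @param responses Integer spike counts, one per trial.
#' @param classes Stimulus class labels, one per trial.
#' @param max_count Optional cap: counts above it are pooled into the top
#'   symbol (small-sample stabilisation; off by default).
#' @return A list of class `"joint_count_table"`: `counts` matrix
#'   (symbols x classes), `response_symbols`, `class_labels`.
#' @export
joint_count_table <- function(responses, classes, max_count = NULL) {
  if (length(responses) != length(classes)) {
    abort("responses and classes must have equal length")
  }
  if (length(responses) == 0) abort("empty table")
  r <- as.integer(responses)
  if (!is.null(max_count)) r <- pmin(r, as.integer(max_count))
  symbols <- sort(unique(r))
  labels <- sort(unique(classes))
  counts <- table(factor(r, levels = symbols),
                  factor(classes, levels = labels))
  counts <- matrix(as.integer(counts), nrow = length(symbols),
                   dimnames = list(symbols, labels))
  structure(list(counts = counts, response_symbols = symbols,
                 class_labels = labels), class = "joint_count_table")
}

#' Plug-in mutual information between responses and stimulus classes
#'
#' Empirical joint probabilities `p(r, s) = n(r, s) / N` are substituted
#' directly into `I(R;S) = sum p(r,s) log2[p(r,s) / (p(r) p(s))]`; terms
#' with `p(r,s) = 0` contribute 0. Also returns the stimulus entropy
#' `H(S)` and conditional entropy `H(S|R)`, with `I = H(S) - H(S|R)` holding
#' to machine precision. No bias correction is applied by default: the
#' plug-in estimate is biased upward by roughly
#' `(|R|-1)(|S|-1) / (2 N ln 2)` bits on independent data, which is why
#' uninformative units read slightly above zero. The Miller-Madow correction
#' (subtracting that bias) is available behind a flag.
#'
#' @param table A [joint_count_table()] or a counts matrix
#'   (symbols x classes).
#' @param miller_madow Apply the Miller-Madow bias correction (default
#'   `FALSE`).
#' @return A one-row tibble with `mi`, `h_s`, `h_s_given_r`, `n_trials`.
#' @export
mutual_information <- function(table, miller_madow = FALSE) {
  counts <- if (inherits(table, "joint_count_table")) table$counts else
    as.matrix(table)
  if (length(counts) == 0 || sum(counts) < 1) abort("empty table")
  if (any(counts < 0)) abort("counts must be >= 0")
  n <- sum(counts)
  p <- counts / n
  pr <- rowSums(p)
  ps <- colSums(p)
  nz <- which(p > 0, arr.ind = TRUE)
  mi <- sum(p[nz] * log2(p[nz] / (pr[nz[, 1]] * ps[nz[, 2]])))
  h_s <- shannon_entropy(ps)
  # H(S|R) = sum_r p(r) H(S | R = r)
  h_sr <- sum(vapply(which(pr > 0), function(i) {
    cond <- p[i, ] / pr[i]
    pr[i] * shannon_entropy(cond)
  }, numeric(1)))
  if (miller_madow) {
    r_occ <- sum(pr > 0)
    s_occ <- sum(ps > 0)
    mi <- max(0, mi - (r_occ - 1) * (s_occ - 1) / (2 * n * log(2)))
  }
  tibble::tibble(mi = mi, h_s = h_s, h_s_given_r = h_sr, n_trials = n)
}

#' Per-unit mutual information from a trial table
#'
#' Builds the joint table of a unit's raw trial spike counts against
#' stimulus classes (movement directions by default) under a condition
#' selector, and applies [mutual_information()].
#'
#' @param trials A trial table from [build_trials()].
#' @param unit_id Unit column.
#' @param laser_on,locomotion Optional condition filters.
#' @param class_map Function mapping direction (degrees) to class labels;
#'   default identity (8-way direction classes). Use
#'   [group_orientations()] for orientation classes.
#' @param max_count Optional response-symbol cap (see
#'   [joint_count_table()]).
#' @param miller_madow See [mutual_information()].
#' @return One-row tibble: `unit_id`, `laser_on`, `locomotion`, `mi`,
#'   `h_s`, `h_s_given_r`, `n_trials`.
#' @export
mi_per_unit <- function(trials, unit_id, laser_on = NULL, locomotion = NULL,
                        class_map = identity, max_count = NULL,
                        miller_madow = FALSE) {
  sel <- rep(TRUE, nrow(trials))
  if (!is.null(laser_on)) sel <- sel & trials$laser_on == laser_on
  if (!is.null(locomotion)) sel <- sel & trials$locomotion == locomotion
  sub <- trials[sel, , drop = FALSE]
  classes <- class_map(sub$direction)
  if (length(unique(classes)) < 2) {
    abort("need at least 2 stimulus classes under this selector")
  }
  jt <- joint_count_table(sub[[unit_id]], classes, max_count = max_count)
  res <- mutual_information(jt, miller_madow = miller_madow)
  dplyr::mutate(res,
                unit_id = unit_id,
                laser_on = if (is.null(laser_on)) NA else laser_on,
                locomotion = if (is.null(locomotion)) NA_character_ else
                  locomotion,
                .before = 1)
}

#' Mutual information of every unit, split by condition
#'
#' @param trials A trial table.
#' @param split Character vector naming condition columns to split by
#'   (subset of `c("laser_on", "locomotion")`).
#' @inheritParams mi_per_unit
#' @return Tibble, one row per unit x condition cell.
#' @export
mi_by_condition <- function(trials, split = c("laser_on"),
                            class_map = identity, max_count = NULL,
                            miller_madow = FALSE) {
  ids <- attr(trials, "unit_ids")
  cells <- unique(as.data.frame(trials)[, split, drop = FALSE])
  purrr::map_dfr(seq_len(nrow(cells)), function(ci) {
    laser <- if ("laser_on" %in% split) cells$laser_on[ci] else NULL
    loco <- if ("locomotion" %in% split) cells$locomotion[ci] else NULL
    purrr::map_dfr(ids, function(id) {
      mi_per_unit(trials, id, laser_on = laser, locomotion = loco,
                  class_map = class_map, max_count = max_count,
                  miller_madow = miller_madow)
    })
  })
}
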