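#' Waveform shape features
#'
#' Extracts the three features used to separate narrow- from broad-spiking
#' cells from a mean spike waveform: the height of the positive peak
#' relative to the negative trough (waveform normalized so the trough is
#' -1), the time from the trough to the following peak (ms), and the slope
#' of the waveform 0.5 ms after the trough (normalized amplitude per ms,
#' central difference by default).
#'
#' @param mean_waveform Numeric waveform (uV) with a unique global minimum.
#' @param waveform_rate Sampling rate, Hz.
#' @param slope_method `"central"` (default) or `"forward"` difference.
#' @param height_convention `"ratio"` (default; peak / |trough|, positive) or
#'   `"difference"` (peak + trough of the normalized waveform). Published
#'   feature tables often print heights with a negative sign; the convention
#'   here is recorded so reports can restore it.
#'
#' @return A one-row tibble with `peak_trough_height`, `trough_to_peak_ms`
#'   and `post_trough_slope`.
#' @export
waveform_features <- function(mean_waveform, waveform_rate,
                              slope_method = c("central", "forward"),
                              height_convention = c("ratio", "difference")) {
  slope_method <- match.arg(slope_method)
  height_convention <- match.arg(height_convention)
  w <- as.numeric(mean_waveform)
  if (length(w) < 3) abort("waveform too short")
  ti <- which.min(w)
  if (sum(w == w[ti]) != 1L) abort("waveform trough is not unique")
  dt_ms <- 1000 / waveform_rate
  if ((length(w) - ti) * dt_ms < 1) {
    abort("waveform must span at least 1 ms after its trough")
  }
  w <- w / abs(w[ti])  # trough = -1

  post <- w[(ti + 1L):length(w)]
  pk_rel <- which.max(post)
  peak <- post[pk_rel]
  ttp_ms <- pk_rel * dt_ms

  height <- if (height_convention == "ratio") peak / 1 else peak + (-1)

  si <- ti + round(0.5 / dt_ms)
  if (si + 1L > length(w)) abort("waveform ends before trough + 0.5 ms")
  slope <- if (slope_method == "central") {
    (w[si + 1L] - w[si - 1L]) / (2 * dt_ms)
  } else {
    (w[si + 1L] - w[si]) / dt_ms
  }

  tibble::tibble(peak_trough_height = height,
                 trough_to_peak_ms = ttp_ms,
                 post_trough_slope = slope)
}

#' Waveform features for every unit in a session
#'
#' @param session A [session()].
#' @inheritParams waveform_features
#' @return Tibble with `unit_id` plus the three feature columns.
#' @export
session_waveform_features <- function(session,
                                      slope_method = "central",
                                      height_convention = "ratio") {
  stopifnot(inherits(session, "optovis_session"))
  purrr::map_dfr(session$units, function(u) {
    dplyr::mutate(
      waveform_features(u$mean_waveform, u$waveform_rate,
                        slope_method, height_convention),
      unit_id = u$unit_id, .before = 1)
  })
}

#' Classify units as narrow- or broad-spiking
#'
#' 2-means clustering of the z-scored three-feature vectors, with
#' deterministic farthest-point initialization (first centre at the unit
#' farthest from the feature mean, second at the unit farthest from the
#' first), so results do not depend on RNG state or unit order. The cluster
#' whose mean trough-to-peak time is larger is labelled BS.
#'
#' @param features Tibble from [session_waveform_features()] (needs
#'   `peak_trough_height`, `trough_to_peak_ms`, `post_trough_slope`; a
#'   `unit_id` column is carried through if present).
#' @return A list of class `"cell_class_result"`: `labels` tibble
#'   (`unit_id` if available, `cell_class`), `centroids` (2 x 3 matrix of
#'   cluster means on the original feature scale), and `sizes`.
#' @export
classify_ns_bs <- function(features) {
  fcols <- c("peak_trough_height", "trough_to_peak_ms", "post_trough_slope")
  if (!all(fcols %in% names(features))) {
    abort("features must contain the three waveform feature columns")
  }
  X <- as.matrix(features[, fcols])
  if (nrow(X) < 2) abort("need at least 2 units to classify")
  if (!all(is.finite(X))) abort("waveform features must be finite")
  sds <- apply(X, 2, sd)
  if (all(sds == 0)) abort("all waveform features identical: degenerate clustering")
  Z <- sweep(X, 2, colMeans(X))
  Z <- sweep(Z, 2, ifelse(sds > 0, sds, 1), "/")

  d0 <- rowSums(Z^2)
  c1 <- which.max(d0)
  d1 <- rowSums(sweep(Z, 2, Z[c1, ])^2)
  c2 <- which.max(d1)
  km <- stats::kmeans(Z, centers = Z[c(c1, c2), , drop = FALSE],
                      iter.max = 100, algorithm = "Lloyd")

  mean_ttp <- tapply(X[, "trough_to_peak_ms"], km$cluster, mean)
  bs_cluster <- as.integer(names(which.max(mean_ttp)))
  labels <- ifelse(km$cluster == bs_cluster, "BS", "NS")

  centroids <- rbind(
    BS = colMeans(X[labels == "BS", , drop = FALSE]),
    NS = colMeans(X[labels == "NS", , drop = FALSE]))

  lab_tbl <- if ("unit_id" %in% names(features)) {
    tibble::tibble(unit_id = features$unit_id, cell_class = labels)
  } else {
    tibble::tibble(cell_class = labels)
  }
  structure(list(labels = lab_tbl, centroids = centroids,
                 sizes = table(labels)),
            class = "cell_class_result")
}

#' @export
print.cell_class_result <- function(x, ...) {
  cat(sprintf("<cell_class_result> %d BS, %d NS\n",
              sum(x$labels$cell_class == "BS"),
              sum(x$labels$cell_class == "NS")))
  print(round(x$centroids, 3))
  invisible(x)
}

#' @export
tidy.cell_class_result <- function(x, ...) x$labels
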