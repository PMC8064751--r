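#' Assemble the trial table from a session
#'
#' Builds one row per grating presentation with the spike count of every unit
#' in a fixed counting window (default: the 1000 ms period beginning 500 ms
#' after stimulus onset), the stimulus direction, whether a laser pulse
#' overlapped the stimulus span, the locomotion state of the trial and its
#' mean speed. The counting window is half-open, `[start, end)`, so adjacent
#' windows partition time.
#'
#' @param session An [session()] object with at least one grating event.
#' @param window_start_offset Seconds between stimulus onset and the start of
#'   the counting window (default 0.5 s).
#' @param window_length Length of the counting window in seconds (default
#'   1 s). `window_start_offset + window_length` must fit inside every
#'   grating's duration.
#' @param cfg A [locomotion_config()].
#'
#' @return A tibble of class `"trial_table"` with columns `trial_idx`,
#'   `onset`, `direction`, `laser_on`, `locomotion`, `mean_speed`, and one
#'   integer count column per unit (named by `unit_id`). Attributes
#'   `unit_ids`, `window_start_offset` and `window_length` record the layout.
#' @export
build_trials <- function(session, window_start_offset = 0.5,
                         window_length = 1.0, cfg = locomotion_config()) {
  stopifnot(inherits(session, "optovis_session"))
  ev <- session$stimulus_events
  gr <- ev[ev$kind == "grating", , drop = FALSE]
  if (nrow(gr) == 0) abort("session has no grating events")
  bad <- which(window_start_offset + window_length > gr$duration + 1e-9)
  if (length(bad)) {
    abort(sprintf(
      "counting window [%g, %g] s extends past the end of the grating at onset %.3f s",
      window_start_offset, window_start_offset + window_length,
      gr$onset[bad[1]]))
  }

  w0 <- gr$onset + window_start_offset
  w1 <- w0 + window_length

  unit_ids <- vapply(session$units, `[[`, character(1), "unit_id")
  counts <- matrix(0L, nrow = nrow(gr), ncol = length(unit_ids),
                   dimnames = list(NULL, unit_ids))
  for (j in seq_along(session$units)) {
    st <- session$units[[j]]$spike_times
    if (length(st) == 0) next
    # half-open [w0, w1): spikes at w1 belong to the next window
    counts[, j] <- findInterval(w1 - 1e-12, st) - findInterval(w0 - 1e-12, st)
  }

  la <- session$laser_events
  laser_on <- vapply(seq_len(nrow(gr)), function(i) {
    if (nrow(la) == 0) return(FALSE)
    any(la$onset < gr$onset[i] + gr$duration[i] - 1e-9 &
        la$onset + la$duration > gr$onset[i] + 1e-9)
  }, logical(1))

  mean_speed <- vapply(seq_len(nrow(gr)), function(i) {
    mean_speed_in_span(gr$onset[i], gr$onset[i] + gr$duration[i],
                       session$speed, cfg)
  }, numeric(1))
  locomotion <- ifelse(mean_speed > cfg$speed_threshold, "running", "still")

  out <- tibble::tibble(
    trial_idx = seq_len(nrow(gr)),
    onset = gr$onset,
    direction = gr$direction,
    laser_on = laser_on,
    locomotion = locomotion,
    mean_speed = mean_speed
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(counts))
  attr(out, "unit_ids") <- unit_ids
  attr(out, "window_start_offset") <- window_start_offset
  attr(out, "window_length") <- window_length
  class(out) <- c("trial_table", class(out))
  out
}

#' Extract the trials x units count matrix from a trial table
#'
#' @param trials A trial table from [build_trials()].
#' @param unit_ids Optional subset/order of unit ids.
#' @return Integer matrix, trials x units.
#' @export
count_matrix <- function(trials, unit_ids = NULL) {
  ids <- unit_ids %||% attr(trials, "unit_ids")
  if (is.null(ids)) {
    ids <- setdiff(names(trials), c("trial_idx", "onset", "direction",
                                    "laser_on", "locomotion", "mean_speed"))
  }
  m <- as.matrix(as.data.frame(trials)[, ids, drop = FALSE])
  storage.mode(m) <- "integer"
  m
}

#' Write / read a trial table as CSV
#'
#' The CSV keeps one row per trial and one count column per unit, so tables
#' are easy to eyeball or load elsewhere. Window parameters travel in the
#' header comment-free via two extra columns on write and are restored on
#' read.
#'
#' @param trials A trial table.
#' @param path File path.
#' @return `write_trials_csv()` returns `path` invisibly; `read_trials_csv()`
#'   returns a trial table tibble.
#' @export
write_trials_csv <- function(trials, path) {
  df <- as.data.frame(trials)
  df$window_start_offset <- attr(trials, "window_start_offset")
  df$window_length <- attr(trials, "window_length")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  wso <- df$window_start_offset[1]
  wl <- df$window_length[1]
  df$window_start_offset <- NULL
  df$window_length <- NULL
  out <- tibble::as_tibble(df)
  meta <- c("trial_idx", "onset", "direction", "laser_on", "locomotion",
            "mean_speed")
  attr(out, "unit_ids") <- setdiff(names(out), meta)
  attr(out, "window_start_offset") <- wso
  attr(out, "window_length") <- wl
  class(out) <- c("trial_table", class(out))
  out
}
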