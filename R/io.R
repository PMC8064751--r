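#' Read and write session containers
#'
#' Sessions are stored as a single JSON file with a fixed group layout
#' (`meta`, `lfp`, `units`, `speed`, `events`). Floats are written at full
#' precision (17 significant digits), so a write/read round trip reproduces
#' every field bit-exactly for integers and text and to full double precision
#' for numerics. Missing required groups raise a schema error naming the
#' field.
#'
#' @param session An [session()] object.
#' @param path File path (conventionally `.json`).
#' @return `write_session()` returns `path` invisibly; `read_session()`
#'   returns a session.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "optovis_session"))
  payload <- list(
    meta = list(subject_id = session$subject_id, region = session$region,
                opsin = session$opsin, duration = session$duration),
    lfp = list(data = session$lfp, rate = session$lfp_rate,
               depths = session$channel_depths,
               shank = session$channel_shank),
    units = lapply(session$units, function(u) {
      list(unit_id = u$unit_id, spike_times = u$spike_times,
           mean_waveform = u$mean_waveform, waveform_rate = u$waveform_rate,
           channel_index = u$channel_index, sort_class = u$sort_class)
    }),
    speed = list(t = session$speed$t, v = session$speed$v),
    events = list(
      stimulus = as.list(session$stimulus_events),
      laser = as.list(session$laser_events)
    )
  )
  json <- jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE,
                           matrix = "rowmajor", null = "null", na = "null")
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such session file: %s", path))
  x <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                          simplifyVector = TRUE, simplifyMatrix = TRUE,
                          simplifyDataFrame = FALSE)
  need <- function(obj, field, where) {
    if (is.null(obj[[field]])) {
      abort(sprintf("session schema error: missing %s/%s", where, field))
    }
    obj[[field]]
  }
  meta <- need(x, "meta", "")
  lfp <- need(x, "lfp", "")
  lfp_data <- lfp$data
  if (is.null(lfp_data) || length(lfp_data) == 0) {
    lfp_data <- matrix(numeric(), 0, 0)
  } else if (!is.matrix(lfp_data)) {
    lfp_data <- matrix(lfp_data, nrow = 1)
  }
  depths <- need(lfp, "depths", "lfp")
  ev <- need(x, "events", "")
  stim <- tibble::as_tibble(lapply(ev$stimulus, unlist_or_empty))
  if (nrow(stim) == 0) stim <- empty_stimulus_events()
  laser <- tibble::as_tibble(lapply(ev$laser, unlist_or_empty))
  if (nrow(laser) == 0) {
    laser <- tibble::tibble(onset = numeric(), duration = numeric())
  }
  units <- lapply(x$units, function(u) {
    unit(unit_id = need(u, "unit_id", "units"),
         spike_times = as.numeric(unlist_or_empty(u$spike_times)),
         mean_waveform = as.numeric(unlist_or_empty(u$mean_waveform)),
         waveform_rate = u$waveform_rate %||% 20000,
         channel_index = u$channel_index %||% 1L,
         sort_class = u$sort_class %||% "unknown")
  })
  sp <- x$speed %||% list(t = numeric(), v = numeric())
  session(
    subject_id = need(meta, "subject_id", "meta"),
    region = need(meta, "region", "meta"),
    opsin = need(meta, "opsin", "meta"),
    lfp = lfp_data,
    lfp_rate = need(lfp, "rate", "lfp"),
    channel_depths = as.numeric(depths),
    channel_shank = as.integer(lfp$shank %||% rep(1L, length(depths))),
    units = units,
    speed = tibble::tibble(t = as.numeric(unlist_or_empty(sp$t)),
                           v = as.numeric(unlist_or_empty(sp$v))),
    stimulus_events = stim,
    laser_events = laser,
    duration = meta$duration %||% NULL
  )
}

unlist_or_empty <- function(x) {
  if (is.null(x)) return(numeric())
  if (is.list(x) && length(x) == 0) return(numeric())
  x
}
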