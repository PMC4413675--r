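## Address-event streams.  Events are held in a plain data.frame with
## columns t_us (integer microseconds, non-decreasing), kind, a1, a2, a3
## (character payload; "-" marks an unused slot).  Kinds:
##   DIR    a1 = array ("ltp"/"stp"), a2 = row, a3 = col   direct spike
##   BCAST  a1 = array, a2 = col                           broadcast spike
##   VIRT   a1 = row, a2 = "exc"/"inh"                     virtual-synapse spike
##   CFG_L  a1 = array, a2 = row*256 + col, a3 = "field=value"
##   CFG_G  a1 = "key=value"
##   OUT    a1 = neuron                                    output / recurrent
## All addresses are 0-based, matching the address-event convention.

EVENT_KINDS <- c("DIR", "BCAST", "VIRT", "CFG_L", "CFG_G", "OUT")

empty_events <- function() {
  data.frame(t_us = integer(0), kind = character(0), a1 = character(0),
             a2 = character(0), a3 = character(0),
             stringsAsFactors = FALSE)
}

new_events <- function(t_us, kind, a1 = "-", a2 = "-", a3 = "-") {
  n <- length(t_us)
  data.frame(t_us = as.integer(round(t_us)),
             kind = rep_len(as.character(kind), n),
             a1 = rep_len(as.character(a1), n),
             a2 = rep_len(as.character(a2), n),
             a3 = rep_len(as.character(a3), n),
             stringsAsFactors = FALSE)
}

validate_events <- function(ev, where = "events") {
  need <- c("t_us", "kind", "a1", "a2", "a3")
  if (!is.data.frame(ev) || !all(need %in% names(ev)))
    stop(where, ": expected a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (nrow(ev) == 0) return(invisible(ev))
  if (any(!ev$kind %in% EVENT_KINDS)) {
    bad <- which(!ev$kind %in% EVENT_KINDS)[1]
    stop(where, ": unknown event kind '", ev$kind[bad], "' at record ", bad,
         call. = FALSE)
  }
  if (any(ev$t_us < 0))
    stop(where, ": negative timestamp at record ", which(ev$t_us < 0)[1],
         call. = FALSE)
  d <- diff(ev$t_us)
  if (any(d < 0))
    stop(where, ": timestamps decrease at record ", which(d < 0)[1] + 1L,
         call. = FALSE)
  invisible(ev)
}

#' Combine event streams
#'
#' Row-binds several event data.frames and stable-sorts by timestamp, so
#' that records with equal times keep their argument order.
#'
#' @param ... Event data.frames (as produced by the event constructors or
#'   [read_events()]).
#' @return A single time-sorted event data.frame.
#' @export
bind_events <- function(...) {
  evs <- Filter(function(x) !is.null(x) && nrow(x) > 0, list(...))
  if (length(evs) == 0) return(empty_events())
  ev <- do.call(rbind, evs)
  ev <- ev[order(ev$t_us), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Event constructors
#'
#' Build event records for the symbolic address-event model: direct spikes
#' to one synapse, broadcast spikes to a column, spikes to a row's virtual
#' synapse, local/global configuration writes, and output (neuron) spikes.
#' Times are given in seconds and stored as integer microseconds; all
#' addresses are 0-based.
#'
#' @param times Spike times in seconds.
#' @param array `"ltp"` or `"stp"`.
#' @param row,col Synapse address, `0..255`.
#' @param type Virtual-synapse branch, `"exc"` or `"inh"`.
#' @param field Local latch name: one of `weight_level`, `exc`, `bc_en`,
#'   `rec_en`, `mon_en`, `set_hi`, `set_low`.
#' @param value Latch value (0/1, or a level for `weight_level`).
#' @param key,  Global register name (`demux_factor` or
#'   `neuron_type_<i>`).
#' @param neuron Source neuron address, `0..255`.
#' @return An event data.frame.
#' @name event_constructors
NULL

#' @rdname event_constructors
#' @export
events_dir <- function(times, array, row, col) {
  stopifnot(array %in% c("ltp", "stp"))
  new_events(times * 1e6, "DIR", array, as.character(row), as.character(col))
}

#' @rdname event_constructors
#' @export
events_bcast <- function(times, array, col) {
  stopifnot(array %in% c("ltp", "stp"))
  new_events(times * 1e6, "BCAST", array, as.character(col))
}

#' @rdname event_constructors
#' @export
events_virt <- function(times, row, type = c("exc", "inh")) {
  type <- match.arg(type)
  new_events(times * 1e6, "VIRT", as.character(row), type)
}

#' @rdname event_constructors
#' @export
events_cfg_local <- function(times, array, row, col, field, value) {
  stopifnot(array %in% c("ltp", "stp"))
  new_events(times * 1e6, "CFG_L", array,
             as.character(as.integer(row) * 256L + as.integer(col)),
             paste0(field, "=", value))
}

#' @rdname event_constructors
#' @export
events_cfg_global <- function(times, key, value) {
  new_events(times * 1e6, "CFG_G", paste0(key, "=", value))
}

#' @rdname event_constructors
#' @export
events_out <- function(times, neuron) {
  new_events(times * 1e6, "OUT", as.character(neuron))
}

#' Read / write event files
#'
#' The event file is plain text, one record per line:
#' `time_us,kind,arg1,arg2,arg3`, with `-` for unused argument slots and
#' times in integer microseconds, non-decreasing.  Malformed lines,
#' unknown kinds and decreasing timestamps are rejected with the offending
#' line number; a write/read round trip reproduces the stream exactly.
#'
#' @param path File path.
#' @param events An event data.frame.
#' @return `read_events()` returns the event data.frame;
#'   `write_events()` returns `path` invisibly.
#' @export
read_events <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_events())
  parts <- strsplit(lines, ",", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 5L))
    stop("read_events: line ", which(nf != 5L)[1],
         ": expected 5 comma-separated fields", call. = FALSE)
  m <- matrix(trimws(unlist(parts)), ncol = 5, byrow = TRUE)
  t_us <- suppressWarnings(as.integer(m[, 1]))
  if (any(is.na(t_us)))
    stop("read_events: line ", which(is.na(t_us))[1],
         ": non-integer timestamp", call. = FALSE)
  ev <- data.frame(t_us = t_us, kind = m[, 2], a1 = m[, 3], a2 = m[, 4],
                   a3 = m[, 5], stringsAsFactors = FALSE)
  if (any(!ev$kind %in% EVENT_KINDS))
    stop("read_events: line ", which(!ev$kind %in% EVENT_KINDS)[1],
         ": unknown kind '", ev$kind[!ev$kind %in% EVENT_KINDS][1], "'",
         call. = FALSE)
  d <- diff(ev$t_us)
  if (any(d < 0))
    stop("read_events: line ", which(d < 0)[1] + 1L,
         ": timestamps decrease", call. = FALSE)
  ev
}

#' @rdname read_events
#' @export
write_events <- function(events, path) {
  validate_events(events, "write_events")
  lines <- sprintf("%d,%s,%s,%s,%s", events$t_us, events$kind,
                   events$a1, events$a2, events$a3)
  writeLines(lines, path)
  invisible(path)
}

## Run code with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(),
                       inherits = FALSE))
              rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Seeded homogeneous Poisson spike train
#'
#' Draws a homogeneous Poisson process on `[t0, t1)`: the event count is
#' Poisson with mean `rate * (t1 - t0)` and times are i.i.d. uniform,
#' returned sorted.  Deterministic for a fixed seed; the caller's RNG
#' state is left untouched.
#'
#' @param rate Mean rate (Hz), `>= 0`.
#' @param t0,t1 Window bounds in seconds, `t1 > t0`.
#' @param seed Integer seed.
#' @return Sorted numeric vector of spike times (s).
#' @export
#' @examples
#' poisson_train(100, 0, 1, seed = 42)[1:5]
poisson_train <- function(rate, t0, t1, seed) {
  if (rate < 0) stop("poisson_train: rate must be >= 0")
  if (t1 <= t0) stop("poisson_train: need t1 > t0")
  if (rate == 0) return(numeric(0))
  with_seed(seed, {
    n <- stats::rpois(1, rate * (t1 - t0))
    sort(stats::runif(n, t0, t1))
  })
}

#' Read a plain-text edge map
#'
#' Edge maps are text grids of `0`/`1` characters, one row per line
#' (whitespace ignored), marking the edge pixels of a stimulus template.
#'
#' @param path File path.
#' @return A logical matrix.
#' @export
read_edge_map <- function(path) {
  lines <- readLines(path)
  lines <- gsub("[[:space:]]", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("read_edge_map: empty file")
  if (length(unique(nchar(lines))) != 1)
    stop("read_edge_map: ragged rows")
  chars <- strsplit(lines, "")
  if (any(!unlist(chars) %in% c("0", "1")))
    stop("read_edge_map: grid must contain only 0 and 1")
  matrix(unlist(chars) == "1", nrow = length(lines), byrow = TRUE)
}

#' Synthetic event-camera scene specification
#'
#' Describes a jittered static-image stimulus as seen by an event camera:
#' the displayed image is a binary edge template, re-displaced ("jittered")
#' at `jitter_rate`, and each displacement makes every edge pixel emit a
#' short Poisson burst of events.  Between presentations a saccadic
#' suppression gap emits no events at all.  Pixel polarity is collapsed to
#' a single event type, and each edge pixel is mapped through
#' `channel_map` to one input column of the programmable synapse array.
#'
#' @param edge_map Logical matrix (edge template), at most 256 cells
#'   unless an explicit `channel_map` subsamples it.
#' @param jitter_rate Displacement rate (Hz), `> 0`.
#' @param event_rate_per_edge_pixel Mean event rate per edge pixel (Hz)
#'   while the image is displayed.
#' @param presentation_s Duration of one presentation (s).
#' @param saccade_gap_s Suppressed interval after the presentation (s).
#' @param channel_map Integer vector mapping edge-pixel linear indices
#'   (column-major, 1-based over `which(edge_map)`) to input columns
#'   `0..255`; must be collision-free.  Default: the pixel's linear index
#'   in the full grid, 0-based.
#' @param burst_window_s Window after each displacement within which the
#'   burst events fall.
#' @param seed Integer seed.
#' @return An object of class `dvs_scene`.
#' @seealso [synth_dvs()]
#' @export
dvs_scene <- function(edge_map, jitter_rate = 10,
                      event_rate_per_edge_pixel = 100,
                      presentation_s = 0.5, saccade_gap_s = 0.1,
                      channel_map = NULL, burst_window_s = 0.01,
                      seed = 1) {
  if (!is.matrix(edge_map) || !is.logical(edge_map))
    stop("dvs_scene: edge_map must be a logical matrix")
  if (jitter_rate <= 0) stop("dvs_scene: jitter_rate must be > 0")
  pix <- which(edge_map)                      # column-major linear indices
  if (is.null(channel_map)) {
    if (length(edge_map) > 256)
      stop("dvs_scene: grids larger than 256 pixels need an explicit ",
           "channel_map")
    channel_map <- pix - 1L                   # identity, 0-based
  }
  if (length(channel_map) != length(pix))
    stop("dvs_scene: channel_map must have one entry per edge pixel")
  if (anyDuplicated(channel_map))
    stop("dvs_scene: channel_map collision (two pixels on one column)")
  if (any(channel_map < 0 | channel_map > 255))
    stop("dvs_scene: channel_map entries must be in 0..255")
  s <- list(edge_map = edge_map, jitter_rate = jitter_rate,
            event_rate_per_edge_pixel = event_rate_per_edge_pixel,
            presentation_s = presentation_s, saccade_gap_s = saccade_gap_s,
            channel_map = as.integer(channel_map),
            burst_window_s = burst_window_s, seed = as.integer(seed))
  class(s) <- "dvs_scene"
  s
}

#' Generate synthetic event-camera events for one presentation
#'
#' Emits broadcast address-events on the programmable-array columns given
#' by the scene's channel map.  Events occur only while the image is
#' displayed (never inside the saccade gap), clustered in Poisson bursts
#' within `burst_window_s` after each jitter displacement; the mean burst
#' size per edge pixel is `event_rate_per_edge_pixel / jitter_rate`.
#' Deterministic for a fixed `(scene, seed)`.
#'
#' @param scene A [dvs_scene()].
#' @param t0 Presentation start time (s).
#' @param seed Optional seed override (defaults to `scene$seed`).
#' @return An event data.frame of `BCAST` events on the `stp` array.
#' @export
synth_dvs <- function(scene, t0 = 0, seed = scene$seed) {
  stopifnot(inherits(scene, "dvs_scene"))
  cols <- scene$channel_map
  n_pix <- length(cols)
  if (n_pix == 0) return(empty_events())
  toggles <- seq(0, scene$presentation_s - 1e-9, by = 1 / scene$jitter_rate)
  mean_burst <- scene$event_rate_per_edge_pixel / scene$jitter_rate
  with_seed(seed, {
    out_t <- list(); out_c <- list(); i <- 0L
    for (tg in toggles) {
      counts <- stats::rpois(n_pix, mean_burst)
      tot <- sum(counts)
      if (tot == 0) next
      w_end <- min(scene$burst_window_s, scene$presentation_s - tg)
      i <- i + 1L
      out_t[[i]] <- t0 + tg + stats::runif(tot, 0, w_end)
      out_c[[i]] <- rep.int(cols, counts)
    }
    if (i == 0L) {
      empty_events()
    } else {
      tt <- unlist(out_t)
      cc <- unlist(out_c)
      o <- order(tt)
      events_bcast(tt[o], "stp", cc[o])
    }
  })
}
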