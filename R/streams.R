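# Event labels allowed in a session event log.
EVENT_VOCABULARY <- c("stand_start", "exercise_start", "rest_start",
                      "rest_end", "sit_start")

#' Create a timed sensor stream
#'
#' A `timed_stream` is one multi-channel sensor signal sampled at (possibly
#' irregular) strictly increasing timestamps, expressed in seconds from
#' session start. It is the unit of storage of a [session_recording()]:
#' force-plate wrenches, arm-rail force triplets, marker trajectories and the
#' stimulation envelope are all timed streams.
#'
#' @param name Text label, e.g. `"plate_left"`.
#' @param timestamps Numeric vector, seconds from session start, strictly
#'   increasing.
#' @param values Numeric matrix with `length(timestamps)` rows, one column
#'   per channel.
#' @param channel_labels Character vector naming the columns of `values`.
#' @param units Per-channel unit tags (`"N"`, `"N.m"`, `"mm"`, `"m"`,
#'   `"fraction"`, `"unitless"`). Recycled if length 1.
#' @param nominal_rate Nominal sampling rate in Hz (informative; the actual
#'   grid is defined by `timestamps`).
#' @return An object of class `timed_stream`.
#' @export
#' @examples
#' ts <- timed_stream("demo", seq(0, 1, by = 0.1),
#'                    cbind(f = sin(seq(0, 1, by = 0.1))), "f", "N", 10)
timed_stream <- function(name, timestamps, values, channel_labels,
                         units = "unitless", nominal_rate = NA_real_) {
  timestamps <- as.numeric(timestamps)
  if (is.null(dim(values))) values <- matrix(as.numeric(values), ncol = 1L)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (length(timestamps) != nrow(values))
    stop("values must have one row per timestamp", call. = FALSE)
  if (length(timestamps) >= 2 && any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != ncol(values))
    stop("channel count must equal label count", call. = FALSE)
  if (length(units) == 1L) units <- rep(units, ncol(values))
  if (length(units) != ncol(values))
    stop("units must be per-channel (or length 1)", call. = FALSE)
  colnames(values) <- channel_labels
  structure(list(name = as.character(name),
                 channel_labels = channel_labels,
                 timestamps = timestamps,
                 values = values,
                 units = as.character(units),
                 nominal_rate = as.numeric(nominal_rate)),
            class = "timed_stream")
}

#' @export
print.timed_stream <- function(x, ...) {
  cat(sprintf("<timed_stream '%s': %d samples x %d channels [%s], span %.3f-%.3f s>\n",
              x$name, length(x$timestamps), ncol(x$values),
              paste(x$channel_labels, collapse = ","),
              if (length(x$timestamps)) min(x$timestamps) else NA,
              if (length(x$timestamps)) max(x$timestamps) else NA))
  invisible(x)
}

#' Create an event log
#'
#' Timestamped session annotations drawn from a fixed vocabulary
#' (`stand_start`, `exercise_start`, `rest_start`, `rest_end`, `sit_start`),
#' used to delimit the exercise phase and rest periods when segmenting
#' cycles.
#'
#' @param time Numeric vector of event times (s), non-decreasing.
#' @param label Character vector of event labels.
#' @return A data.frame of class `event_log` with columns `time`, `label`.
#' @export
event_log <- function(time = numeric(0), label = character(0)) {
  time <- as.numeric(time)
  label <- as.character(label)
  if (length(time) != length(label))
    stop("time and label must have equal length", call. = FALSE)
  if (length(time) >= 2 && any(diff(time) < 0))
    stop("event times must be non-decreasing", call. = FALSE)
  bad <- setdiff(unique(label), EVENT_VOCABULARY)
  if (length(bad))
    stop("unknown event label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  structure(data.frame(time = time, label = label,
                       stringsAsFactors = FALSE),
            class = c("event_log", "data.frame"))
}

#' Assemble a session recording
#'
#' The container for one exercise session: participant metadata plus a named
#' set of synchronized [timed_stream()]s sharing one uniform time grid, and
#' an [event_log()]. The canonical stream set is `plate_left` / `plate_right`
#' (6 channels Fx,Fy,Fz,Mx,My,Mz), `rail_left` / `rail_right` (3 channels),
#' `markers` (3 channels per marker; the clavicle marker `clav_x/y/z` is
#' mandatory) and `stim_envelope` (channels LEFT, RIGHT).
#'
#' Coordinates: X lateral (positive toward the participant's right),
#' Y anterior, Z vertical upward. Plate Fz is positive for upward support
#' force; a pull on the arm rails is recorded negative.
#'
#' @param participant_id Text identifier.
#' @param session_index Positive integer session number.
#' @param body_mass Participant mass in kg (> 0).
#' @param wheelchair_mass Wheelchair mass in kg.
#' @param streams Named list of [timed_stream()]s on a common uniform grid.
#' @param events An [event_log()].
#' @param grid_rate Grid rate in Hz (default 100).
#' @param check If `TRUE` (default), verify the common-grid and clavicle
#'   invariants.
#' @return An object of class `session_recording`.
#' @export
session_recording <- function(participant_id, session_index, body_mass,
                              wheelchair_mass = NA_real_, streams = list(),
                              events = event_log(), grid_rate = 100,
                              check = TRUE) {
  if (!is.numeric(body_mass) || body_mass <= 0)
    stop("body_mass must be > 0", call. = FALSE)
  session_index <- as.integer(session_index)
  if (session_index < 1L) stop("session_index must be >= 1", call. = FALSE)
  if (length(streams) && is.null(names(streams)))
    stop("streams must be named", call. = FALSE)
  if (check && length(streams)) {
    grids <- lapply(streams, function(s) s$timestamps)
    ref <- grids[[1L]]
    for (g in grids) {
      if (length(g) != length(ref) || max(abs(g - ref)) > 1e-9)
        stop("all streams must share one uniform time grid; use synchronize()",
             call. = FALSE)
    }
    if (length(ref) >= 2) {
      dt <- diff(ref)
      if (max(abs(dt - 1 / grid_rate)) > 1e-6)
        stop("stream grid spacing does not match grid_rate", call. = FALSE)
    }
    if ("markers" %in% names(streams) &&
        !all(c("clav_x", "clav_z") %in% streams$markers$channel_labels))
      stop("markers stream must include the clavicle channels clav_x/clav_z",
           call. = FALSE)
  }
  structure(list(participant_id = as.character(participant_id),
                 session_index = session_index,
                 body_mass = as.numeric(body_mass),
                 wheelchair_mass = as.numeric(wheelchair_mass),
                 streams = streams,
                 events = events,
                 grid_rate = as.numeric(grid_rate)),
            class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf("<session_recording %s #%d: %.1f kg, %d streams, %d events, %g Hz>\n",
              x$participant_id, x$session_index, x$body_mass,
              length(x$streams), nrow(x$events), x$grid_rate))
  for (s in x$streams) print(s)
  invisible(x)
}

#' Resample a stream onto a uniform grid
#'
#' Linearly interpolates every channel of `stream` onto the uniform grid
#' `t0, t0 + 1/rate, ...` up to (and including, when it lands on the grid)
#' `t1`. No extrapolation: `[t0, t1]` must lie within the stream's span.
#'
#' @param stream A [timed_stream()] with at least 2 samples.
#' @param rate Target rate in Hz.
#' @param t0,t1 Grid span in seconds; defaults to the stream's own span.
#' @return A [timed_stream()] on the uniform grid.
#' @export
resample_to_grid <- function(stream, rate, t0 = NULL, t1 = NULL) {
  stopifnot(inherits(stream, "timed_stream"))
  n <- length(stream$timestamps)
  if (n < 2) stop("stream must have at least 2 samples", call. = FALSE)
  span <- range(stream$timestamps)
  if (is.null(t0)) t0 <- span[1L]
  if (is.null(t1)) t1 <- span[2L]
  if (t0 < span[1L] - 1e-9 || t1 > span[2L] + 1e-9 || t1 < t0)
    stop(sprintf("grid span [%g, %g] outside stream span [%g, %g]",
                 t0, t1, span[1L], span[2L]), call. = FALSE)
  grid <- t0 + seq(0L, floor((t1 - t0) * rate + 1e-9)) / rate
  vals <- apply(stream$values, 2L, function(col)
    stats::approx(stream$timestamps, col, xout = grid, rule = 1)$y)
  if (length(grid) == 1L) vals <- matrix(vals, nrow = 1L)
  timed_stream(stream$name, grid, vals, stream$channel_labels,
               stream$units, rate)
}

#' Synchronize streams onto a common grid
#'
#' Computes the intersection of all stream spans and resamples every stream
#' onto a shared uniform grid at `rate` over that intersection. This is the
#' offline equivalent of the acquisition layer's stream synchronization: no
#' sample outside any input stream's span is ever invented.
#'
#' @param streams Named list of [timed_stream()]s.
#' @param rate Common grid rate in Hz.
#' @return Named list of resampled streams sharing one grid.
#' @export
synchronize <- function(streams, rate) {
  if (!length(streams)) stop("no streams to synchronize", call. = FALSE)
  spans <- vapply(streams, function(s) range(s$timestamps), numeric(2))
  t0 <- max(spans[1L, ])
  t1 <- min(spans[2L, ])
  if (t1 <= t0)
    stop("streams do not overlap in time; cannot synchronize", call. = FALSE)
  lapply(streams, resample_to_grid, rate = rate, t0 = t0, t1 = t1)
}

#' Write a session recording to a directory container
#'
#' The container is one directory holding `session.json` (metadata, masses,
#' grid rate, event log, stream inventory) plus one comma-separated table per
#' stream (`time` column followed by one column per channel, with a one-line
#' header of channel labels). Plain-text and diff-able by design.
#'
#' @param rec A [session_recording()].
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @seealso [read_session()]
#' @export
write_session <- function(rec, path) {
  stopifnot(inherits(rec, "session_recording"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    participant_id = rec$participant_id,
    session_index = rec$session_index,
    body_mass = rec$body_mass,
    wheelchair_mass = rec$wheelchair_mass,
    grid_rate = rec$grid_rate,
    events = list(time = rec$events$time, label = rec$events$label),
    streams = lapply(rec$streams, function(s) list(
      name = s$name, file = paste0(s$name, ".csv"),
      channel_labels = s$channel_labels, units = s$units,
      nominal_rate = s$nominal_rate))
  )
  jsonlite::write_json(meta, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  for (s in rec$streams) {
    dt <- data.table::data.table(time = s$timestamps)
    for (j in seq_along(s$channel_labels))
      data.table::set(dt, j = s$channel_labels[j], value = s$values[, j])
    data.table::fwrite(dt, file.path(path, paste0(s$name, ".csv")))
  }
  invisible(path)
}

#' Read a session recording from a directory container
#'
#' Inverse of [write_session()]. `read_session(write_session(rec, p))`
#' reproduces `rec` to 6 decimal places in stream values and exactly in
#' metadata.
#'
#' @param path Container directory.
#' @return A [session_recording()].
#' @export
read_session <- function(path) {
  meta_file <- file.path(path, "session.json")
  if (!file.exists(meta_file))
    stop("session container format error: missing 'session.json' in ", path,
         call. = FALSE)
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  ev <- if (length(meta$events$time))
    event_log(meta$events$time, meta$events$label) else event_log()
  streams <- list()
  sm <- meta$streams
  for (nm in names(sm)) {
    info <- sm[[nm]]
    f <- file.path(path, info$file)
    if (!file.exists(f))
      stop("session container format error: missing stream file '",
           info$file, "'", call. = FALSE)
    dt <- data.table::fread(f)
    streams[[nm]] <- timed_stream(info$name, dt$time,
                                  as.matrix(dt[, -1, drop = FALSE]),
                                  info$channel_labels, info$units,
                                  info$nominal_rate)
  }
  session_recording(meta$participant_id, meta$session_index, meta$body_mass,
                    meta$wheelchair_mass, streams, ev, meta$grid_rate)
}

# Exclusion intervals implied by an event log: everything before
# exercise_start, everything after sit_start, and rest_start..rest_end pairs.
# Returns a 2-column matrix (start, end); used by peak detection.
event_exclusion_intervals <- function(events, t_min, t_max) {
  out <- NULL
  es <- events$time[events$label == "exercise_start"]
  if (length(es)) out <- rbind(out, c(t_min, es[1L]))
  ss <- events$time[events$label == "sit_start"]
  if (length(ss)) out <- rbind(out, c(ss[1L], t_max))
  rs <- events$time[events$label == "rest_start"]
  re <- events$time[events$label == "rest_end"]
  for (i in seq_along(rs)) {
    end_i <- re[re > rs[i]]
    out <- rbind(out, c(rs[i], if (length(end_i)) end_i[1L] else t_max))
  }
  if (is.null(out)) matrix(numeric(0), ncol = 2L) else out
}
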