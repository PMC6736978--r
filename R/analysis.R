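#' Convert a force to percent body weight
#'
#' `100 * force / (body_mass * g)` with g = 9.81 m/s^2. Sign is preserved
#' (a pull on the arm rails stays negative).
#'
#' @param force Force(s) in N.
#' @param body_mass Body mass in kg (> 0).
#' @return Force as %BW.
#' @export
to_bw_percent <- function(force, body_mass) {
  if (!is.numeric(body_mass) || body_mass <= 0)
    stop("body_mass must be positive", call. = FALSE)
  100 * force / (body_mass * GRAVITY)
}

# Strict local maxima of a numeric trace; plateau runs count once with the
# peak placed on the first sample of the run. Boundary runs are excluded
# (a maximum needs a lower neighbour on both sides).
local_maxima_idx <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  if (k < 3) return(integer(0))
  mid <- 2:(k - 1L)
  is_max <- r$values[mid] > r$values[mid - 1L] &
    r$values[mid] > r$values[mid + 1L]
  starts[mid][is_max]
}

#' Detect exercise-cycle peaks in a vertical GRF trace
#'
#' Implements the cycle-segmentation rule: strict local maxima of the
#' vertical plate force with amplitude at least `min_frac` of body weight,
#' thinned so that no two retained peaks are closer than `min_sep` seconds
#' (among conflicting candidates the larger amplitude wins, processed in
#' descending amplitude order). Candidates falling inside excluded
#' intervals (before `exercise_start`, after `sit_start`, and labelled rest
#' periods) are dropped, as are peaks whose `min_sep` window is truncated
#' by the recording boundary (edge rule).
#'
#' @param fz A single-channel [timed_stream()] (or a stream containing an
#'   `Fz` channel) on a uniform grid.
#' @param body_mass Body mass in kg.
#' @param min_frac Peak threshold as a fraction of body weight (default
#'   0.5).
#' @param min_sep Minimum separation between retained peaks (s, default 5).
#' @param events Optional [event_log()] defining excluded intervals.
#' @param edge_policy `"drop"` (default) removes peaks closer than
#'   `min_sep` to either end of the trace; `"keep"` retains and flags them.
#' @return data.frame with columns `time`, `value` (N), `bw_pct`,
#'   `edge_truncated`, sorted by time.
#' @export
detect_cycle_peaks <- function(fz, body_mass, min_frac = 0.5, min_sep = 5,
                               events = NULL,
                               edge_policy = c("drop", "keep")) {
  edge_policy <- match.arg(edge_policy)
  stopifnot(inherits(fz, "timed_stream"))
  if (body_mass <= 0) stop("body_mass must be positive", call. = FALSE)
  col <- if ("Fz" %in% fz$channel_labels) "Fz" else fz$channel_labels[1L]
  v <- fz$values[, col]
  tt <- fz$timestamps
  if (!length(v)) stop("empty stream", call. = FALSE)
  thr <- min_frac * body_mass * GRAVITY
  idx <- local_maxima_idx(v)
  idx <- idx[v[idx] >= thr]
  if (!is.null(events) && length(idx)) {
    excl <- event_exclusion_intervals(events, min(tt), max(tt))
    if (nrow(excl)) {
      keep <- rep(TRUE, length(idx))
      for (r in seq_len(nrow(excl)))
        keep <- keep & !(tt[idx] >= excl[r, 1L] & tt[idx] <= excl[r, 2L])
      idx <- idx[keep]
    }
  }
  # greedy separation: descending amplitude, ties broken by earlier time;
  # retained times kept sorted so each candidate only checks its two
  # nearest retained neighbours
  if (length(idx) > 1) {
    ord <- idx[order(-v[idx], tt[idx])]
    chosen_t <- numeric(0)
    chosen_i <- integer(0)
    for (i in ord) {
      ti <- tt[i]
      pos <- findInterval(ti, chosen_t)
      ok <- (pos == 0L || ti - chosen_t[pos] >= min_sep) &&
        (pos == length(chosen_t) || chosen_t[pos + 1L] - ti >= min_sep)
      if (ok) {
        chosen_t <- append(chosen_t, ti, after = pos)
        chosen_i <- append(chosen_i, i, after = pos)
      }
    }
    idx <- sort(chosen_i)
  }
  edge <- tt[idx] - min(tt) < min_sep | max(tt) - tt[idx] < min_sep
  if (edge_policy == "drop") {
    idx <- idx[!edge]
    edge <- edge[!edge]
  }
  data.frame(time = tt[idx], value = v[idx],
             bw_pct = to_bw_percent(v[idx], body_mass),
             edge_truncated = edge)
}

#' Sample all streams of a recording at given times
#'
#' Returns each stream's value at each query time: the grid sample when the
#' time lies on the grid, linear interpolation otherwise. Query times must
#' lie within the recording span.
#'
#' @param rec A [session_recording()].
#' @param times Numeric vector of query times (s).
#' @return Named list (one element per stream) of matrices
#'   `length(times) x n_channels`.
#' @export
sample_at_peaks <- function(rec, times) {
  stopifnot(inherits(rec, "session_recording"))
  if (!length(rec$streams)) stop("recording has no streams", call. = FALSE)
  span <- range(rec$streams[[1L]]$timestamps)
  if (length(times) && (min(times) < span[1L] - 1e-9 ||
                        max(times) > span[2L] + 1e-9))
    stop("query time outside recording span", call. = FALSE)
  lapply(rec$streams, function(s) {
    k <- ncol(s$values)
    if (!length(times)) {
      out <- matrix(numeric(0), 0L, k)
    } else {
      out <- vapply(seq_len(k), function(j)
        stats::approx(s$timestamps, s$values[, j], xout = times, rule = 1)$y,
        numeric(length(times)))
      if (length(times) == 1L) out <- matrix(out, nrow = 1L)
    }
    colnames(out) <- s$channel_labels
    out
  })
}

#' Clavicle lean angle
#'
#' Signed lateral lean in degrees: the two-argument arctangent of the
#' lateral displacement of the clavicle marker from its reference position
#' over its vertical height above the plate surface. Positive = lean toward
#' the participant's right; 0 deg = the centered start-of-cycle posture.
#'
#' @param clavicle_xyz Numeric 3-vector (x, y, z) in metres, or an n x 3
#'   matrix.
#' @param reference_xyz Reference (centered) clavicle position; only its x
#'   is used.
#' @return Angle(s) in degrees.
#' @export
lean_angle <- function(clavicle_xyz, reference_xyz) {
  if (is.null(dim(clavicle_xyz)))
    clavicle_xyz <- matrix(clavicle_xyz, nrow = 1L)
  x <- clavicle_xyz[, 1L]
  z <- clavicle_xyz[, 3L]
  if (any(z <= 0))
    stop("geometry error: clavicle must be above the plate surface",
         call. = FALSE)
  ref_x <- reference_xyz[1L]
  atan2(x - ref_x, z) * 180 / pi
}

#' Range of motion over successive left/right cycle pairs
#'
#' For each consecutive pair of opposite-side cycles, the range of motion is
#' the sum of the absolute lean angles, `|theta_left| + |theta_right|`.
#' Pairs are non-overlapping in time order; a cycle followed by another on
#' the same side is skipped, and a trailing unpaired cycle is dropped.
#'
#' @param cycles data.frame of time-ordered cycles with columns `side` and
#'   `lean_angle` (degrees), as produced by [analyze_session()].
#' @return Numeric vector of per-pair ROM values (degrees); empty when
#'   fewer than one valid pair exists.
#' @export
range_of_motion <- function(cycles) {
  n <- nrow(cycles)
  out <- numeric(0)
  i <- 1L
  while (i < n) {
    if (cycles$side[i] != cycles$side[i + 1L]) {
      out <- c(out, abs(cycles$lean_angle[i]) + abs(cycles$lean_angle[i + 1L]))
      i <- i + 2L
    } else i <- i + 1L
  }
  out
}

#' Run the full analysis pipeline on one session
#'
#' Detects cycle peaks on each plate, merges them by time (simultaneous
#' bilateral peaks resolve to the larger), samples the co-recorded limb
#' forces and clavicle position at each peak, converts forces to %BW, and
#' computes the signed lean angle per cycle. The angular reference is the
#' mean clavicle position over the centered phase between `stand_start`
#' (or the recording start) and `min_sep` before the first detected peak
#' (`reference = "session_start"`), or the per-cycle start position
#' (`reference = "cycle_start"`).
#'
#' @param rec A [session_recording()].
#' @param min_frac Peak threshold as fraction of BW (default 0.5).
#' @param min_sep Minimum peak separation in s (default 5), applied per
#'   plate.
#' @param reference Angular reference policy (see above).
#' @return data.frame of class `exercise_cycles`, one row per cycle:
#'   `side`, `peak_time`, `peak_fz`, `peak_bw_pct`, `left_leg_n`,
#'   `right_leg_n`, `left_arm_n`, `right_arm_n`, the same as %BW
#'   (`*_bw_pct`), `arm_bw_pct` (total magnitude), `legs_bw_pct` (total),
#'   and `lean_angle` (degrees).
#' @export
analyze_session <- function(rec, min_frac = 0.5, min_sep = 5,
                            reference = c("session_start", "cycle_start")) {
  reference <- match.arg(reference)
  stopifnot(inherits(rec, "session_recording"))
  pk_l <- detect_cycle_peaks(rec$streams$plate_left, rec$body_mass,
                             min_frac, min_sep, rec$events)
  pk_r <- detect_cycle_peaks(rec$streams$plate_right, rec$body_mass,
                             min_frac, min_sep, rec$events)
  pk_l$side <- rep("L", nrow(pk_l))
  pk_r$side <- rep("R", nrow(pk_r))
  peaks <- rbind(pk_l, pk_r)
  peaks <- peaks[order(peaks$time), , drop = FALSE]
  # simultaneous bilateral peaks (pathological): keep the larger
  if (nrow(peaks) > 1) {
    same <- which(diff(peaks$time) < 1e-9)
    drop <- integer(0)
    for (i in same)
      drop <- c(drop, if (peaks$value[i] >= peaks$value[i + 1L]) i + 1L else i)
    if (length(drop)) peaks <- peaks[-unique(drop), , drop = FALSE]
  }
  if (!nrow(peaks)) {
    out <- data.frame(side = character(0), peak_time = numeric(0),
                      peak_fz = numeric(0), peak_bw_pct = numeric(0),
                      left_leg_n = numeric(0), right_leg_n = numeric(0),
                      left_arm_n = numeric(0), right_arm_n = numeric(0),
                      left_leg_bw_pct = numeric(0),
                      right_leg_bw_pct = numeric(0),
                      arm_bw_pct = numeric(0), legs_bw_pct = numeric(0),
                      lean_angle = numeric(0))
    class(out) <- c("exercise_cycles", "data.frame")
    return(out)
  }
  at <- sample_at_peaks(rec, peaks$time)
  fzl <- at$plate_left[, "Fz"]
  fzr <- at$plate_right[, "Fz"]
  arml <- at$rail_left[, "Fz"]
  armr <- at$rail_right[, "Fz"]
  theta <- rep(NA_real_, nrow(peaks))
  if (!is.null(rec$streams$markers)) {
    m <- rec$streams$markers
    clav <- at$markers[, c("clav_x", "clav_y", "clav_z"), drop = FALSE]
    ts0 <- rec$events$time[rec$events$label == "stand_start"]
    t_lo <- if (length(ts0)) ts0[1L] else min(m$timestamps)
    if (reference == "session_start") {
      t_hi <- max(t_lo + 1e-3, peaks$time[1L] - min_sep)
      win <- m$timestamps >= t_lo & m$timestamps <= t_hi
      if (!any(win)) win <- m$timestamps <= m$timestamps[1L] + 5
      ref <- c(mean(m$values[win, "clav_x"]), 0,
               mean(m$values[win, "clav_z"]))
      theta <- lean_angle(clav, ref)
    } else {
      # per-cycle reference: clavicle position half a separation before
      # each peak, clamped to the recording start
      ref_t <- pmax(min(m$timestamps), peaks$time - min_sep / 2)
      refs <- sample_at_peaks(rec, ref_t)$markers
      theta <- vapply(seq_len(nrow(peaks)), function(i)
        lean_angle(clav[i, , drop = FALSE], refs[i, ]), numeric(1))
    }
  }
  out <- data.frame(
    side = peaks$side, peak_time = peaks$time, peak_fz = peaks$value,
    peak_bw_pct = peaks$bw_pct,
    left_leg_n = fzl, right_leg_n = fzr,
    left_arm_n = arml, right_arm_n = armr,
    left_leg_bw_pct = to_bw_percent(fzl, rec$body_mass),
    right_leg_bw_pct = to_bw_percent(fzr, rec$body_mass),
    arm_bw_pct = to_bw_percent(abs(arml) + abs(armr), rec$body_mass),
    legs_bw_pct = to_bw_percent(fzl + fzr, rec$body_mass),
    lean_angle = theta)
  class(out) <- c("exercise_cycles", "data.frame")
  out
}

#' Summarize a session's detected cycles
#'
#' Per-session aggregates of the cycle table: cycle count, per-side and
#' overall mean/SD of the supporting-leg peak load (%BW), arm support
#' mean/SD (%BW), range-of-motion mean/SD (degrees), and the within-session
#' profile of peak %BW versus cycle index. When `mature_after` is given
#' (habituation ramp duration), post-habituation aggregates over cycles
#' with `peak_time > mature_after` are reported alongside the all-cycle
#' values.
#'
#' @param rec The analyzed [session_recording()].
#' @param cycles The [analyze_session()] output for `rec`.
#' @param mature_after Optional time (s) after which cycles count as
#'   post-habituation.
#' @return List of class `session_summary`.
#' @export
summarize_session <- function(rec, cycles, mature_after = NULL) {
  n <- nrow(cycles)
  rom <- range_of_motion(cycles)
  msd <- function(x) if (length(x)) c(mean = mean(x), sd = stats::sd(x))
                     else c(mean = NA_real_, sd = NA_real_)
  mature <- if (!is.null(mature_after)) cycles$peak_time > mature_after
            else rep(TRUE, n)
  out <- list(
    participant_id = rec$participant_id,
    session_index = rec$session_index,
    cycle_count = n,
    defined = n > 0L,
    peak_bw = msd(cycles$peak_bw_pct),
    peak_bw_left = msd(cycles$peak_bw_pct[cycles$side == "L"]),
    peak_bw_right = msd(cycles$peak_bw_pct[cycles$side == "R"]),
    peak_bw_mature = msd(cycles$peak_bw_pct[mature]),
    arm_bw = msd(cycles$arm_bw_pct),
    legs_bw = msd(cycles$legs_bw_pct),
    rom = msd(rom),
    rom_values = rom,
    profile = data.frame(cycle_index = seq_len(n),
                         peak_time = cycles$peak_time,
                         side = cycles$side,
                         peak_bw_pct = cycles$peak_bw_pct))
  class(out) <- "session_summary"
  out
}

#' @export
print.session_summary <- function(x, ...) {
  cat(sprintf("<session_summary %s #%d: %d cycles, peak %.2f +/- %.2f %%BW, arm %.2f %%BW, ROM %.2f deg>\n",
              x$participant_id, x$session_index, x$cycle_count,
              x$peak_bw["mean"], x$peak_bw["sd"], x$arm_bw["mean"],
              x$rom["mean"]))
  invisible(x)
}

#' Moving average of a within-session peak profile
#'
#' Centered-window running mean used to track the within-session stability
#' of the supporting-leg peak load (window trimmed at the profile edges).
#'
#' @param x Numeric vector (e.g. per-cycle peak %BW).
#' @param window Window length in cycles (default 20).
#' @return Numeric vector, same length as `x`.
#' @export
moving_average <- function(x, window = 20L) {
  n <- length(x)
  if (!n) return(numeric(0))
  half <- window %/% 2L
  vapply(seq_len(n), function(i)
    mean(x[max(1L, i - half):min(n, i + half)]), numeric(1))
}
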