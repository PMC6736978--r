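#' Define a cyclic stimulation schedule
#'
#' Parameters of the posture-shifting FES pattern: two muscle groups (LEFT
#' and RIGHT lower limb) alternate between a full-stimulation ON plateau and
#' an OFF plateau, joined by linear transitions. The envelope modulates the
#' per-channel pulse WIDTH; pulse amplitude and rate are fixed device
#' constants (138 mA into the nominal 1 kOhm || 100 nF load, 30 Hz).
#'
#' One period is `P = on_time + off_time + 2 * transition_time`. The phase
#' origin `t = 0` is the start of the LEFT ON plateau and the RIGHT group is
#' the LEFT group shifted by `P/2`, which with the experimental parameters
#' (5 s ON, 3 s OFF, 1 s transition) makes opposite ON plateaus tile the
#' period exactly.
#'
#' @param on_time ON plateau duration (s).
#' @param off_time OFF plateau duration (s).
#' @param transition_time Ramp duration between plateaus (s).
#' @param off_pct Stimulation level during the OFF plateau as a fraction of
#'   the ON level, in \[0, 1\]. 0 means no stimulation at rest.
#' @param frequency Pulse rate in Hz (device constant, 30).
#' @param amplitude Pulse amplitude in mA (device constant, 138; metadata).
#' @param channel_group Map of channels 1..16 to `"LEFT"`, `"RIGHT"` or
#'   `"UNASSIGNED"`. Default assigns 1–8 LEFT, 9–16 RIGHT.
#' @param on_pulse_width Per-channel ON pulse width in microseconds,
#'   each in \[0, 500\]. Recycled to 16 channels.
#' @return An object of class `stim_schedule`.
#' @export
#' @examples
#' sched <- stim_schedule(5, 3, 1)
#' validate_schedule(sched)
stim_schedule <- function(on_time = 5, off_time = 3, transition_time = 1,
                          off_pct = 0, frequency = 30, amplitude = 138,
                          channel_group = NULL,
                          on_pulse_width = 300) {
  if (any(c(on_time, off_time, transition_time) <= 0))
    stop("stimulation times must be positive", call. = FALSE)
  if (off_pct < 0 || off_pct > 1)
    stop("off_pct must lie in [0, 1]", call. = FALSE)
  if (is.null(channel_group))
    channel_group <- rep(c("LEFT", "RIGHT"), each = 8L)
  channel_group <- as.character(channel_group)
  if (!all(channel_group %in% c("LEFT", "RIGHT", "UNASSIGNED")))
    stop("channel_group entries must be LEFT, RIGHT or UNASSIGNED",
         call. = FALSE)
  if (length(on_pulse_width) == 1L)
    on_pulse_width <- rep(on_pulse_width, length(channel_group))
  if (length(on_pulse_width) != length(channel_group))
    stop("on_pulse_width must match channel count", call. = FALSE)
  if (any(on_pulse_width < 0 | on_pulse_width > 500))
    stop("pulse widths must lie in [0, 500] microseconds", call. = FALSE)
  active <- unique(channel_group[channel_group != "UNASSIGNED"])
  if (!length(active))
    stop("at least one channel must be assigned to an active group",
         call. = FALSE)
  structure(list(on_time = on_time, off_time = off_time,
                 transition_time = transition_time, off_pct = off_pct,
                 frequency = frequency, amplitude = amplitude,
                 channel_group = channel_group,
                 on_pulse_width = on_pulse_width),
            class = "stim_schedule")
}

#' Period of a stimulation schedule
#' @param sched A [stim_schedule()].
#' @return Cycle period in seconds.
#' @export
schedule_period <- function(sched) {
  sched$on_time + sched$off_time + 2 * sched$transition_time
}

#' Evaluate the cyclic stimulation envelope
#'
#' Dimensionless stimulation level in `[off_pct, 1]` for one group at times
#' `t` (s). Per period and group: ON plateau (`on_time`), linear ramp down
#' (`transition_time`), OFF plateau at `off_pct` (`off_time`), linear ramp
#' up. The RIGHT group is the LEFT group delayed by half a period, so while
#' one side holds its ON plateau the other rests, with overlapping
#' transitions shifting the load between sides.
#'
#' @param sched A [stim_schedule()].
#' @param group `"LEFT"` or `"RIGHT"`.
#' @param t Numeric vector of times (s), `>= 0`.
#' @return Numeric vector of levels, same length as `t`.
#' @export
envelope_level <- function(sched, group, t) {
  group <- match.arg(group, c("LEFT", "RIGHT"))
  if (!any(sched$channel_group == group))
    stop("no channel assigned to group ", group,
         "; configuration error", call. = FALSE)
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  P <- schedule_period(sched)
  if (group == "RIGHT") t <- t + P / 2
  ph <- t %% P
  on <- sched$on_time; tr <- sched$transition_time
  off <- sched$off_time; lo <- sched$off_pct
  lvl <- numeric(length(ph))
  # ON plateau
  i <- ph < on
  lvl[i] <- 1
  # ramp down
  i <- ph >= on & ph < on + tr
  lvl[i] <- 1 - (1 - lo) * (ph[i] - on) / tr
  # OFF plateau
  i <- ph >= on + tr & ph < on + tr + off
  lvl[i] <- lo
  # ramp up
  i <- ph >= on + tr + off
  lvl[i] <- lo + (1 - lo) * (ph[i] - (on + tr + off)) / tr
  lvl
}

#' Check the geometry of a stimulation schedule
#'
#' With the two groups half a period apart, one group's ON plateau tiles
#' exactly against the other's rest phase when
#' `on_time == off_time + 2 * transition_time`. Longer ON plateaus overlap
#' (both sides simultaneously fully stimulated for part of the cycle),
#' shorter ones leave a gap (neither side fully stimulated).
#'
#' @param sched A [stim_schedule()].
#' @return List with `period`, `geometry` (`"tiling"`, `"overlap"` or
#'   `"gap"`) and `mismatch` (s; positive overlap or gap duration, 0 when
#'   tiling).
#' @export
validate_schedule <- function(sched) {
  stopifnot(inherits(sched, "stim_schedule"))
  rest <- sched$off_time + 2 * sched$transition_time
  d <- sched$on_time - rest
  list(period = schedule_period(sched),
       geometry = if (d > 0) "overlap" else if (d < 0) "gap" else "tiling",
       mismatch = abs(d))
}

#' Generate the pulse train for one channel
#'
#' Emits the constant-rate pulse events for `channel` over `[t0, t1)`:
#' pulses at `t0 + k / frequency`, each with width
#' `envelope_level(t) * on_pulse_width[channel]` (zero-width pulses are
#' omitted) and the fixed device amplitude.
#'
#' @param sched A [stim_schedule()].
#' @param channel Channel index (must be assigned to a group).
#' @param t0,t1 Window in seconds, `t0 < t1`.
#' @param envelope Optional override envelope function `f(t)` (used for
#'   continuous mode); defaults to the channel group's cyclic envelope.
#' @return A data.frame of class `pulse_train` with columns `time` (s),
#'   `width` (microseconds), `amplitude` (mA).
#' @export
generate_pulse_train <- function(sched, channel, t0, t1, envelope = NULL) {
  stopifnot(inherits(sched, "stim_schedule"))
  if (t0 >= t1) stop("t0 must precede t1", call. = FALSE)
  grp <- sched$channel_group[channel]
  if (is.na(grp) || grp == "UNASSIGNED")
    stop("channel ", channel, " is unassigned; configuration error",
         call. = FALSE)
  times <- t0 + seq(0L, ceiling((t1 - t0) * sched$frequency)) / sched$frequency
  times <- times[times < t1 - 1e-12]
  lvl <- if (is.null(envelope)) envelope_level(sched, grp, times)
         else envelope(times)
  width <- lvl * sched$on_pulse_width[channel]
  keep <- width > 0
  structure(data.frame(time = times[keep], width = width[keep],
                       amplitude = rep(sched$amplitude, sum(keep))),
            class = c("pulse_train", "data.frame"))
}

#' Constant-level (continuous) stimulation envelope
#'
#' During sit-to-stand the operator applies continuous stimulation that is
#' later switched to the cyclic pattern. This returns the constant envelope
#' function together with the channels it drives; [cyclic_switch_time()]
#' gives the next instant at which switching to the cyclic pattern is
#' discontinuity-free.
#'
#' @param level Stimulation level in \[0, 1\].
#' @param channels Integer channel indices driven at `level`.
#' @return List of class `continuous_mode` with `level`, `channels` and
#'   `envelope` (a function of `t`).
#' @export
continuous_mode <- function(level, channels = 1:16) {
  if (level < 0 || level > 1)
    stop("continuous level must lie in [0, 1]; configuration error",
         call. = FALSE)
  force(level)
  structure(list(level = level, channels = as.integer(channels),
                 envelope = function(t) rep(level, length(t))),
            class = "continuous_mode")
}

#' Next discontinuity-free switch instant into the cyclic pattern
#'
#' Returns the earliest time `>= t` at which the cyclic envelope of `group`
#' equals `level`, restricted to plateau boundaries (plateau starts) so the
#' handover from continuous to cyclic stimulation introduces no level jump.
#' A `level` between `off_pct` and 1 is matched on the ramp instead.
#'
#' @param sched A [stim_schedule()].
#' @param group `"LEFT"` or `"RIGHT"`.
#' @param t Earliest admissible time (s).
#' @param level Continuous level being handed over, in \[`off_pct`, 1\].
#' @return Switch time in seconds.
#' @export
cyclic_switch_time <- function(sched, group = "LEFT", t = 0, level = 1) {
  P <- schedule_period(sched)
  on <- sched$on_time; tr <- sched$transition_time
  lo <- sched$off_pct
  if (level < lo || level > 1)
    stop("level must lie in [off_pct, 1]", call. = FALSE)
  # phase (within the group's own cycle) at which the envelope equals level
  ph_target <- if (level == 1) 0
  else if (level == lo) on + tr
  else on + tr * (1 - level) / (1 - lo)   # on the down ramp
  shift <- if (group == "RIGHT") P / 2 else 0
  # absolute times with this phase: ph_target - shift + k P
  t0 <- ph_target - shift
  k <- ceiling((t - t0 - 1e-12) / P)
  t0 + k * P
}

#' Rasterize envelope levels onto a time grid
#'
#' Helper for plotting and for building the recorded `stim_envelope` stream:
#' samples the LEFT and RIGHT envelopes at `rate` Hz over `[t0, t1]`.
#'
#' @param sched A [stim_schedule()].
#' @param rate Sampling rate (Hz).
#' @param t0,t1 Window (s).
#' @return A [timed_stream()] named `stim_envelope` with channels
#'   `LEFT`, `RIGHT`.
#' @export
rasterize_envelope <- function(sched, rate, t0, t1) {
  grid <- t0 + seq(0L, floor((t1 - t0) * rate + 1e-9)) / rate
  timed_stream("stim_envelope", grid,
               cbind(LEFT = envelope_level(sched, "LEFT", grid),
                     RIGHT = envelope_level(sched, "RIGHT", grid)),
               c("LEFT", "RIGHT"), "fraction", rate)
}

#' Read a stimulation schedule from a JSON or YAML config file
#'
#' Keys mirror the [stim_schedule()] arguments.
#'
#' @param path Config file (`.json` or `.yaml`/`.yml`).
#' @return A [stim_schedule()].
#' @export
read_schedule <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(stim_schedule, cfg[intersect(names(cfg), names(formals(stim_schedule)))])
}
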