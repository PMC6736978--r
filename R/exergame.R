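#' Skier position from the leg load distribution
#'
#' The virtual skier's horizontal position is the normalized left/right
#' vertical load imbalance, `(fz_right - fz_left) / (fz_right + fz_left)`,
#' clipped to `[-1, 1]`. Positive is toward the participant's right.
#'
#' @param fz_left,fz_right Vertical plate forces (N); their sum must be
#'   positive.
#' @return Dimensionless position in `[-1, 1]` (vectorized).
#' @export
skier_position <- function(fz_left, fz_right) {
  tot <- fz_left + fz_right
  if (any(tot <= 0))
    stop("undefined skier position: non-positive total leg load",
         call. = FALSE)
  pmax(-1, pmin(1, (fz_right - fz_left) / tot))
}

#' Hoop schedule from the stimulation pattern
#'
#' One hoop per ON plateau, on the side of the stimulated group, presented
#' at the plateau midpoint. Sides therefore alternate L, R, L, ... at
#' half-period spacing.
#'
#' @param sched A [stim_schedule()].
#' @param duration Game duration (s); every plateau starting before
#'   `duration` contributes a hoop.
#' @return data.frame with columns `side` (`"L"`/`"R"`) and `time` (s).
#' @export
hoop_schedule <- function(sched, duration) {
  P <- schedule_period(sched)
  kL <- floor((duration - 1e-9) / P)
  starts_L <- P * 0:kL
  kR <- floor((duration - P / 2 - 1e-9) / P)
  starts_R <- if (kR >= 0) P / 2 + P * 0:kR else numeric(0)
  hoops <- data.frame(
    side = c(rep("L", length(starts_L)), rep("R", length(starts_R))),
    time = c(starts_L, starts_R) + sched$on_time / 2)
  hoops <- hoops[order(hoops$time), , drop = FALSE]
  rownames(hoops) <- NULL
  hoops
}

#' Initial game state
#' @param hoops Hoop schedule from [hoop_schedule()].
#' @return List of class `game_state` with `skier_x`, `hoops`, `next_hoop`,
#'   `score`, `arm_warning`.
#' @export
game_state <- function(hoops = NULL) {
  structure(list(skier_x = 0, hoops = hoops, next_hoop = 1L, score = 0L,
                 arm_warning = FALSE),
            class = "game_state")
}

#' Score the pending hoop
#'
#' The hoop target position is +0.5 (right hoop) or -0.5 (left hoop); the
#' skier scores iff its position at the hoop time is within `band` of the
#' target.
#'
#' @param state A [game_state()] with a pending hoop.
#' @param skier_x Skier position at the hoop time.
#' @param band Scoring half-width (default 0.25).
#' @return Updated `game_state` (score possibly incremented, `next_hoop`
#'   advanced).
#' @export
update_game <- function(state, skier_x, band = 0.25) {
  stopifnot(inherits(state, "game_state"))
  if (is.null(state$hoops) || state$next_hoop > nrow(state$hoops))
    stop("no hoop pending", call. = FALSE)
  side <- state$hoops$side[state$next_hoop]
  target <- if (side == "R") 0.5 else -0.5
  if (abs(skier_x - target) <= band) state$score <- state$score + 1L
  state$skier_x <- skier_x
  state$next_hoop <- state$next_hoop + 1L
  state
}

#' Excessive arm-support warning
#'
#' True iff the (push or pull) arm support magnitude exceeds the threshold,
#' strictly.
#'
#' @param arm_bw_pct Arm support as %BW (magnitude, >= 0).
#' @param threshold Warning threshold in %BW (default 10).
#' @return Logical (vectorized).
#' @export
arm_warning <- function(arm_bw_pct, threshold = 10) {
  if (any(arm_bw_pct < 0))
    stop("arm_bw_pct is a magnitude and must be >= 0", call. = FALSE)
  arm_bw_pct > threshold
}

#' Replay a session through the exergame logic
#'
#' Rendering-free closed-loop check: builds the hoop schedule for the
#' session's exercise phase, evaluates the skier position from the recorded
#' plate forces at each hoop time, and scores every hoop. Also emits a
#' per-hoop trace with the arm-warning flag.
#'
#' @param rec A [session_recording()] with plate and rail streams.
#' @param sched The [stim_schedule()] that drove the session.
#' @param band Scoring half-width (default 0.25).
#' @param arm_threshold Arm warning threshold in %BW (default 10).
#' @return List with `score`, `n_hoops` and `trace` (data.frame: `time`,
#'   `side`, `skier_x`, `scored`, `arm_warning`).
#' @export
play_session <- function(rec, sched, band = 0.25, arm_threshold = 10) {
  stopifnot(inherits(rec, "session_recording"))
  ev <- rec$events
  t_ex <- ev$time[ev$label == "exercise_start"][1L]
  t_sit <- ev$time[ev$label == "sit_start"][1L]
  if (is.na(t_ex)) t_ex <- 0
  if (is.na(t_sit)) t_sit <- max(rec$streams[[1L]]$timestamps)
  hoops <- hoop_schedule(sched, t_sit - t_ex)
  hoops$time <- hoops$time + t_ex
  hoops <- hoops[hoops$time < t_sit, , drop = FALSE]
  at <- sample_at_peaks(rec, hoops$time)
  fzl <- at$plate_left[, "Fz"]
  fzr <- at$plate_right[, "Fz"]
  sx <- skier_position(fzl, fzr)
  arm_pct <- to_bw_percent(abs(at$rail_left[, "Fz"]) +
                             abs(at$rail_right[, "Fz"]), rec$body_mass)
  st <- game_state(hoops)
  scored <- logical(nrow(hoops))
  for (i in seq_len(nrow(hoops))) {
    before <- st$score
    st <- update_game(st, sx[i], band)
    scored[i] <- st$score > before
  }
  st$arm_warning <- any(arm_warning(arm_pct, arm_threshold))
  list(score = st$score, n_hoops = nrow(hoops),
       trace = data.frame(time = hoops$time, side = hoops$side,
                          skier_x = sx, scored = scored,
                          arm_warning = arm_warning(arm_pct, arm_threshold)))
}
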