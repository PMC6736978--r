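#' Average a co-planar load-cell pair
#'
#' Each arm-rail force degree of freedom is measured by two co-planar load
#' cells at opposite ends of the rail; reporting their arithmetic mean
#' cancels the torque produced by off-centre hand placement.
#'
#' @param cell_a,cell_b Raw (or calibrated) readings; vectors of equal
#'   length.
#' @return Element-wise mean.
#' @export
pair_average <- function(cell_a, cell_b) {
  if (any(!is.finite(cell_a)) || any(!is.finite(cell_b)))
    stop("non-finite load-cell reading", call. = FALSE)
  (cell_a + cell_b) / 2
}

#' Fit a linear load-cell calibration
#'
#' Least-squares fit of `force = gain * raw + offset` to a static-weight
#' sweep, with `force = mass * g` (g = 9.81 m/s^2). The reference sweep
#' spans 0–58.5 kg in 4.5 kg increments (14 points).
#'
#' @param applied_masses Applied masses in kg (>= 2 distinct values).
#' @param readings Raw sensor readings (abstract counts/volts), same length.
#' @return List of class `rail_calibration` with `gain` (N per raw unit),
#'   `offset` (N), `residual_rms` (N) and `n_points`.
#' @export
#' @examples
#' masses <- seq(0, 58.5, by = 4.5)
#' raw <- (masses * 9.81 - 5) / 2        # true gain 2, offset 5
#' fit_linear_calibration(masses, raw)
fit_linear_calibration <- function(applied_masses, readings) {
  if (length(applied_masses) != length(readings))
    stop("masses and readings must have equal length", call. = FALSE)
  if (length(unique(applied_masses)) < 2)
    stop("calibration fit error: need at least 2 distinct masses",
         call. = FALSE)
  if (stats::var(readings) == 0)
    stop("calibration fit error: zero variance in readings", call. = FALSE)
  force <- applied_masses * GRAVITY
  fit <- stats::lm(force ~ readings)
  gain <- unname(coef(fit)[2L])
  if (!is.finite(gain) || gain == 0)
    stop("calibration fit error: degenerate gain", call. = FALSE)
  structure(list(gain = gain, offset = unname(coef(fit)[1L]),
                 residual_rms = sqrt(mean(stats::residuals(fit)^2)),
                 n_points = length(readings)),
            class = "rail_calibration")
}

#' Apply a rail calibration
#' @param cal A `rail_calibration`.
#' @param raw Raw readings.
#' @return Calibrated force in N.
#' @export
apply_rail_calibration <- function(cal, raw) cal$gain * raw + cal$offset

#' Create a force-plate calibration
#'
#' @param matrix 6x6 numeric matrix mapping raw plate output to the wrench
#'   (Fx, Fy, Fz, Mx, My, Mz); must be invertible.
#' @return Object of class `plate_calibration`.
#' @export
plate_calibration <- function(matrix = diag(6)) {
  matrix <- as.matrix(matrix)
  if (!all(dim(matrix) == c(6L, 6L)))
    stop("plate calibration matrix must be 6x6", call. = FALSE)
  if (abs(det(matrix)) < .Machine$double.eps^0.5)
    stop("plate calibration matrix must be invertible", call. = FALSE)
  structure(list(matrix = matrix), class = "plate_calibration")
}

#' Convert raw plate output to a wrench
#'
#' Matrix–vector product of the supplier calibration matrix with the raw
#' 6-vector (or 6-column matrix of samples), yielding
#' (Fx, Fy, Fz, Mx, My, Mz) in N and N·m.
#'
#' @param raw Numeric 6-vector, or an n x 6 matrix of samples.
#' @param cal A [plate_calibration()].
#' @return Calibrated wrench(es), same shape as `raw`.
#' @export
apply_plate_matrix <- function(raw, cal) {
  stopifnot(inherits(cal, "plate_calibration"))
  if (is.null(dim(raw))) {
    if (length(raw) != 6L)
      stop("raw plate vector must have 6 components", call. = FALSE)
    return(as.numeric(cal$matrix %*% raw))
  }
  if (ncol(raw) != 6L)
    stop("raw plate matrix must have 6 columns", call. = FALSE)
  t(cal$matrix %*% t(raw))
}

#' Participant weight from a combined frame measurement
#'
#' The participant is weighed in the frame while seated; their mass is the
#' recorded combined mass minus the wheelchair mass.
#'
#' @param combined_mass Combined participant + wheelchair mass (kg).
#' @param wheelchair_mass Wheelchair mass (kg).
#' @return Participant body mass in kg (stored as `body_mass` on session
#'   recordings).
#' @export
measure_participant_weight <- function(combined_mass, wheelchair_mass) {
  if (wheelchair_mass <= 0 || combined_mass <= 0)
    stop("masses must be positive", call. = FALSE)
  m <- combined_mass - wheelchair_mass
  if (m <= 0)
    stop("combined mass must exceed wheelchair mass", call. = FALSE)
  m
}

#' Save / load calibrations as JSON
#'
#' Rail calibrations store per-DoF gain/offset; plate calibrations store the
#' 6x6 matrix row-major.
#'
#' @param cal A `rail_calibration` or [plate_calibration()].
#' @param path JSON file path.
#' @return `write_calibration`: `path` invisibly. `read_calibration`: the
#'   calibration object.
#' @export
write_calibration <- function(cal, path) {
  if (inherits(cal, "plate_calibration")) {
    jsonlite::write_json(list(type = "plate",
                              matrix = as.vector(t(cal$matrix))),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(list(type = "rail", gain = cal$gain,
                              offset = cal$offset,
                              residual_rms = cal$residual_rms,
                              n_points = cal$n_points),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(x$type, "plate"))
    plate_calibration(matrix(x$matrix, 6L, 6L, byrow = TRUE))
  else
    structure(list(gain = x$gain, offset = x$offset,
                   residual_rms = x$residual_rms, n_points = x$n_points),
              class = "rail_calibration")
}
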