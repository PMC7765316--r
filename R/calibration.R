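#' @useDynLib trajheat, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rlnorm sd cov coef lm
#' @importFrom utils write.csv read.csv modifyList
NULL

#' Standard gravity vector
#'
#' Gravity in the global frame, z-up convention: `c(0, 0, -9.81)` m/s^2.
#' @return Numeric 3-vector.
#' @export
gravity_vector <- function() c(0, 0, -9.81)

#' Test a matrix for being a proper rotation
#'
#' Checks orthonormality (`t(R) %*% R == I`) and `det(R) == +1`, both within
#' `tol`.
#'
#' @param R A 3x3 numeric matrix.
#' @param tol Numeric tolerance (default `1e-8`).
#' @return `TRUE` or `FALSE`.
#' @export
is_rotation <- function(R, tol = 1e-8) {
  if (!is.matrix(R) || !all(dim(R) == c(3L, 3L)) || !all(is.finite(R))) {
    return(FALSE)
  }
  ortho <- max(abs(crossprod(R) - diag(3))) <= tol
  ortho && abs(det(R) - 1) <= tol
}

assert_rotation <- function(R, what = "rotation matrix", tol = 1e-8) {
  if (!is_rotation(R, tol = tol)) {
    stop(sprintf("%s must be a proper 3x3 rotation (orthonormal, det +1)", what),
         call. = FALSE)
  }
  invisible(R)
}

#' Elementary rotation matrices
#'
#' Right-handed rotations about the global x, y and z axes, acting on column
#' vectors by left multiplication.
#'
#' @param theta Angle in radians.
#' @return A 3x3 rotation matrix.
#' @export
rot_x <- function(theta) {
  c1 <- cos(theta); s1 <- sin(theta)
  matrix(c(1, 0, 0, 0, c1, s1, 0, -s1, c1), 3, 3)
}

#' @rdname rot_x
#' @export
rot_y <- function(theta) {
  c1 <- cos(theta); s1 <- sin(theta)
  matrix(c(c1, 0, -s1, 0, 1, 0, s1, 0, c1), 3, 3)
}

#' @rdname rot_x
#' @export
rot_z <- function(theta) {
  c1 <- cos(theta); s1 <- sin(theta)
  matrix(c(c1, s1, 0, -s1, c1, 0, 0, 0, 1), 3, 3)
}

#' Draw a uniformly random rotation matrix
#'
#' QR-based Haar sampling; the sign of the diagonal is fixed so the result is
#' uniform over SO(3).
#'
#' @return A 3x3 rotation matrix.
#' @export
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Per-sensor calibration state
#'
#' Holds the calibration rotation, the virtual bone rotation and the gravity
#' vector used to clean and localize raw IMU readings.
#'
#' @param R_calib 3x3 rotation applied after gravity removal.
#' @param R_bone 3x3 virtual bone orientation.
#' @param g Gravity vector in the global frame, m/s^2.
#' @return An object of class `calibration_state`.
#' @export
calibration_state <- function(R_calib = diag(3), R_bone = diag(3),
                              g = gravity_vector()) {
  assert_rotation(R_calib, "R_calib")
  assert_rotation(R_bone, "R_bone")
  stopifnot(is.numeric(g), length(g) == 3L, all(is.finite(g)))
  structure(list(R_calib = R_calib, R_bone = R_bone, g = as.numeric(g)),
            class = "calibration_state")
}

#' Calibration state from a static calibration pose
#'
#' The convention for synthetic data: with the subject holding a known static
#' pose, `R_calib` is the inverse (= transpose) of the orientation measured at
#' calibration time and `R_bone` is the identity.
#'
#' @param R_imu_at_calibration Sensor orientation measured during the
#'   calibration pose.
#' @param g Gravity vector.
#' @return A `calibration_state`.
#' @export
calibration_from_pose <- function(R_imu_at_calibration, g = gravity_vector()) {
  assert_rotation(R_imu_at_calibration, "R_imu_at_calibration")
  calibration_state(R_calib = t(R_imu_at_calibration), R_bone = diag(3), g = g)
}

#' Gravity-clean and localize a raw acceleration reading
#'
#' Rotates the sensor-frame acceleration into the global frame, removes
#' gravity, and applies the calibration rotation:
#' `a_local = R_calib %*% (R_imu %*% a_imu - g)`.
#'
#' @param a_imu Raw 3-axis acceleration in the sensor frame, m/s^2.
#' @param R_imu 3x3 sensor-to-global orientation.
#' @param calib A [calibration_state()].
#' @return The localized acceleration, a numeric 3-vector.
#' @export
calibrate_acceleration <- function(a_imu, R_imu, calib) {
  stopifnot(is.numeric(a_imu), length(a_imu) == 3L, all(is.finite(a_imu)))
  assert_rotation(R_imu, "R_imu")
  stopifnot(inherits(calib, "calibration_state"))
  a_nog <- drop(R_imu %*% a_imu) - calib$g
  drop(calib$R_calib %*% a_nog)
}

#' Localize a raw orientation reading
#'
#' `R_local = R_calib %*% R_imu %*% R_bone`.
#'
#' @inheritParams calibrate_acceleration
#' @return A 3x3 rotation matrix.
#' @export
calibrate_orientation <- function(R_imu, calib) {
  assert_rotation(R_imu, "R_imu")
  stopifnot(inherits(calib, "calibration_state"))
  calib$R_calib %*% R_imu %*% calib$R_bone
}

#' Normalize a localized reading to the body root
#'
#' Expresses a sensor's localized acceleration and orientation relative to the
#' body-root (pelvis) sensor: `a_norm = t(R_root) %*% (a_local - a_root)` and
#' `R_norm = t(R_root) %*% R_local`. The inverse of `R_root` is taken as its
#' transpose; orthonormality is enforced on input.
#'
#' @param a_local Localized sensor acceleration, 3-vector.
#' @param R_local Localized sensor orientation, 3x3 rotation.
#' @param a_root Localized root acceleration, 3-vector.
#' @param R_root Localized root orientation, 3x3 rotation.
#' @return A list with elements `a_normalized` and `R_normalized`.
#' @export
normalize_to_root <- function(a_local, R_local, a_root, R_root) {
  stopifnot(is.numeric(a_local), length(a_local) == 3L,
            is.numeric(a_root), length(a_root) == 3L)
  assert_rotation(R_local, "R_local")
  assert_rotation(R_root, "R_root")
  Rt <- t(R_root)
  list(a_normalized = drop(Rt %*% (a_local - a_root)),
       R_normalized = Rt %*% R_local)
}

#' Dead reckoning by double integration
#'
#' Integrates an acceleration series twice with the semi-implicit Euler
#' update `v[t+1] = v[t] + dt * a[t+1]`, `x[t+1] = x[t] + dt * v[t+1]`.
#' Under a constant acceleration bias the position error grows quadratically
#' in elapsed time, which is why raw double integration cannot track body
#' points over more than a few seconds; this function exists as that drift
#' diagnostic and as the round-trip check for the synthetic IMU generator.
#'
#' @param a Acceleration series: an `n x 3` matrix (or a numeric 3-vector for
#'   a single step), m/s^2. Row t is the acceleration at step t, used to
#'   update from step t-1.
#' @param dt Time step, seconds.
#' @param x0 Initial position (default origin).
#' @param v0 Initial velocity (default zero).
#' @return An `(n+1) x 3` matrix of positions; row 1 is `x0`.
#' @export
dead_reckon <- function(a, dt, x0 = c(0, 0, 0), v0 = c(0, 0, 0)) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 3L, byrow = TRUE)
  stopifnot(dt > 0, ncol(a) == 3L, all(is.finite(a)),
            length(x0) == 3L, length(v0) == 3L)
  n <- nrow(a)
  if (n == 0L) return(matrix(x0, 1L, 3L))
  # v_t = v0 + dt * cumsum(a); x_t = x0 + dt * cumsum(v)
  v <- sweep(apply(a * dt, 2L, cumsum), 2L, v0, "+")
  if (n == 1L) v <- matrix(v, 1L, 3L)
  x <- sweep(apply(v * dt, 2L, cumsum), 2L, x0, "+")
  if (n == 1L) x <- matrix(x, 1L, 3L)
  rbind(matrix(x0, 1L, 3L), x, deparse.level = 0L)
}

#' Fit the drift growth exponent of dead-reckoned error
#'
#' Runs dead reckoning on a constant acceleration bias and regresses
#' log(position error) on log(elapsed time). A slope of 2 is the quadratic
#' drift signature.
#'
#' @param bias Constant acceleration bias vector, m/s^2.
#' @param dt Time step, seconds.
#' @param n_steps Number of integration steps.
#' @return The fitted log-log slope (scalar).
#' @export
drift_loglog_slope <- function(bias = c(0.1, 0, 0), dt = 1 / 60, n_steps = 600L) {
  a <- matrix(bias, n_steps, 3L, byrow = TRUE)
  x <- dead_reckon(a, dt)
  err <- sqrt(rowSums(x^2))[-1L]
  tt <- dt * seq_len(n_steps)
  # skip the first few steps where the discrete sum is farthest from t^2
  keep <- seq(from = max(3L, n_steps %/% 20L), to = n_steps)
  unname(coef(lm(log(err[keep]) ~ log(tt[keep])))[2L])
}

#' Write / read per-sensor calibration states as CSV
#'
#' One row per sensor: `sensor_id`, the nine `R_calib` entries
#' (column-major, `Rc1`..`Rc9`) and the nine `R_bone` entries
#' (`Rb1`..`Rb9`). Gravity is part of the run configuration, not the file.
#'
#' @param calibrations Named list of [calibration_state()] objects (names
#'   are sensor IDs).
#' @param path CSV path.
#' @param g Gravity vector to attach to the states on reading.
#' @return `write_calibration_csv` returns `path` invisibly;
#'   `read_calibration_csv` a named list of calibration states.
#' @export
write_calibration_csv <- function(calibrations, path) {
  stopifnot(length(calibrations) >= 1L, !is.null(names(calibrations)))
  rows <- lapply(names(calibrations), function(id) {
    cal <- calibrations[[id]]
    stopifnot(inherits(cal, "calibration_state"))
    as.data.frame(c(list(sensor_id = id),
                    stats::setNames(as.list(as.vector(cal$R_calib)),
                                    paste0("Rc", 1:9)),
                    stats::setNames(as.list(as.vector(cal$R_bone)),
                                    paste0("Rb", 1:9))))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calibration_csv
#' @export
read_calibration_csv <- function(path, g = gravity_vector()) {
  df <- read.csv(path)
  out <- lapply(seq_len(nrow(df)), function(i) {
    calibration_state(
      R_calib = matrix(as.numeric(df[i, paste0("Rc", 1:9)]), 3, 3),
      R_bone = matrix(as.numeric(df[i, paste0("Rb", 1:9)]), 3, 3),
      g = g)
  })
  stats::setNames(out, df$sensor_id)
}
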