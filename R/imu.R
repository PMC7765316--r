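#' Synthesize IMU readings from a vertex trajectory
#'
#' Produces per-frame, per-vertex accelerometer and orientation readings that
#' are physically consistent with a position trajectory: linear acceleration
#' is the second central finite difference of position, gravity is added
#' back, and the result is expressed in the sensor frame, so that the
#' calibration pipeline (gravity removal, localization, root normalization)
#' inverts the construction exactly up to O(dt^2) discretization error.
#'
#' @param seq A [motion_sequence()] with at least 3 frames.
#' @param gravity Gravity vector in the global frame (default
#'   [gravity_vector()]).
#' @param orientation_model `"identity"` (sensor axes aligned with the global
#'   frame) or `"velocity-tangent"` (x-axis along the vertex velocity,
#'   z-axis the gravity-orthogonalized up direction; falls back to identity
#'   where the vertex is at rest).
#' @param noise_sd Accelerometer noise SD, m/s^2 (seeded by the caller's RNG
#'   state).
#' @return An object of class `imu_recording`: list with `a` (frames x
#'   vertices x 3, sensor frame), `R` (frames x vertices x 3 x 3,
#'   sensor-to-global), `sampling_rate`, `subject_id`, `label`, `gravity`.
#' @export
imu_from_trajectory <- function(seq, gravity = gravity_vector(),
                                orientation_model = c("identity", "velocity-tangent"),
                                noise_sd = 0) {
  stopifnot(inherits(seq, "motion_sequence"))
  orientation_model <- match.arg(orientation_model)
  p <- seq$positions
  n <- dim(p)[1L]; nv <- dim(p)[2L]
  if (n < 3L) stop("need at least 3 frames to differentiate twice", call. = FALSE)
  dt <- 1 / seq$sampling_rate

  a_lin <- array(0, dim = dim(p))
  idx <- 2:(n - 1L)
  a_lin[idx, , ] <- (p[idx + 1L, , , drop = FALSE] -
                       2 * p[idx, , , drop = FALSE] +
                       p[idx - 1L, , , drop = FALSE]) / dt^2
  a_lin[1L, , ] <- a_lin[2L, , ]
  a_lin[n, , ] <- a_lin[n - 1L, , ]

  R <- array(0, dim = c(n, nv, 3L, 3L))
  if (orientation_model == "identity") {
    R[, , 1L, 1L] <- 1; R[, , 2L, 2L] <- 1; R[, , 3L, 3L] <- 1
  } else {
    v <- array(0, dim = dim(p))
    v[idx, , ] <- (p[idx + 1L, , , drop = FALSE] -
                     p[idx - 1L, , , drop = FALSE]) / (2 * dt)
    v[1L, , ] <- v[2L, , ]; v[n, , ] <- v[n - 1L, , ]
    up <- c(0, 0, 1)
    for (t in seq_len(n)) for (vx in seq_len(nv)) {
      vv <- v[t, vx, ]
      sp <- sqrt(sum(vv^2))
      zc <- up - if (sp > 1e-6) sum(up * vv / sp) * vv / sp else 0
      nz <- sqrt(sum(zc^2))
      if (sp > 1e-6 && nz > 1e-6) {
        xa <- vv / sp; za <- zc / nz
        ya <- c(za[2L] * xa[3L] - za[3L] * xa[2L],
                za[3L] * xa[1L] - za[1L] * xa[3L],
                za[1L] * xa[2L] - za[2L] * xa[1L])
        R[t, vx, , ] <- cbind(xa, ya, za)
      } else {
        R[t, vx, , ] <- diag(3)
      }
    }
  }

  # sensor-frame reading: a_imu = R^T (a_lin + g), so R a_imu - g = a_lin
  a_imu <- array(0, dim = dim(p))
  for (vx in seq_len(nv)) {
    ag <- sweep(a_lin[, vx, ], 2L, gravity, "+")
    if (orientation_model == "identity") {
      a_imu[, vx, ] <- ag
    } else {
      for (t in seq_len(n)) {
        a_imu[t, vx, ] <- drop(t(R[t, vx, , ]) %*% ag[t, ])
      }
    }
  }
  if (noise_sd > 0) {
    a_imu <- a_imu + array(rnorm(length(a_imu), 0, noise_sd), dim = dim(a_imu))
  }
  structure(list(a = a_imu, R = R, sampling_rate = seq$sampling_rate,
                 subject_id = seq$subject_id, label = seq$label,
                 gravity = gravity),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  d <- dim(x$a)
  cat(sprintf("<imu_recording> subject %s, '%s': %d frames x %d sensors @ %g Hz\n",
              x$subject_id, x$label, d[1L], d[2L], x$sampling_rate))
  invisible(x)
}

#' Calibrate and root-normalize a whole IMU recording
#'
#' Applies gravity removal and localization to every frame of every sensor,
#' then expresses each non-root sensor relative to the root sensor. With the
#' default calibration (identity `R_calib`/`R_bone`) this is the plain
#' global-frame pipeline used for synthetic recordings.
#'
#' @param rec An [imu_from_trajectory()] recording.
#' @param calibrations Optional list of [calibration_state()] per sensor
#'   (recycled if length 1); default identity calibration with the
#'   recording's gravity.
#' @param root_vertex Name or index of the root sensor (default `"root"`,
#'   the lower-back/pelvis placement).
#' @param vertices Names of the sensor channels (default
#'   [tracked_vertices()]).
#' @return List with `a_norm` (frames x sensors x 3) and `R_norm` (frames x
#'   sensors x 3 x 3), root included (identically zero / identity).
#' @export
normalize_recording <- function(rec, calibrations = NULL,
                                root_vertex = "root",
                                vertices = tracked_vertices()) {
  stopifnot(inherits(rec, "imu_recording"))
  n <- dim(rec$a)[1L]; nv <- dim(rec$a)[2L]
  if (is.null(calibrations)) {
    calibrations <- list(calibration_state(g = rec$gravity))
  }
  if (length(calibrations) == 1L) calibrations <- rep(calibrations, nv)
  ri <- if (is.character(root_vertex)) match(root_vertex, vertices) else root_vertex
  stopifnot(!is.na(ri), ri >= 1L, ri <= nv)

  a_loc <- array(0, dim = dim(rec$a))
  R_loc <- array(0, dim = dim(rec$R))
  for (t in seq_len(n)) for (vx in seq_len(nv)) {
    cal <- calibrations[[vx]]
    Rimu <- rec$R[t, vx, , ]
    a_loc[t, vx, ] <- drop(cal$R_calib %*% (drop(Rimu %*% rec$a[t, vx, ]) - cal$g))
    R_loc[t, vx, , ] <- cal$R_calib %*% Rimu %*% cal$R_bone
  }
  a_norm <- array(0, dim = dim(rec$a))
  R_norm <- array(0, dim = dim(rec$R))
  for (t in seq_len(n)) {
    Rr <- R_loc[t, ri, , ]
    ar <- a_loc[t, ri, ]
    Rt <- t(Rr)
    for (vx in seq_len(nv)) {
      a_norm[t, vx, ] <- drop(Rt %*% (a_loc[t, vx, ] - ar))
      R_norm[t, vx, , ] <- Rt %*% R_loc[t, vx, , ]
    }
  }
  list(a_norm = a_norm, R_norm = R_norm, root_index = ri)
}

#' Per-frame feature matrix of a normalized recording
#'
#' Stacks, for every non-root sensor, the 3 normalized acceleration
#' components and the 9 entries of the normalized orientation matrix. With
#' six sensors this yields 5 x 12 = 60 features per frame — the raw-signal
#' input width of the sequence classifiers.
#'
#' @param norm Output of [normalize_recording()].
#' @return A `frames x (12 * (sensors - 1))` numeric matrix.
#' @export
signal_features <- function(norm) {
  n <- dim(norm$a_norm)[1L]; nv <- dim(norm$a_norm)[2L]
  keep <- setdiff(seq_len(nv), norm$root_index)
  out <- matrix(0, n, 12L * length(keep))
  j <- 0L
  for (vx in keep) {
    out[, j + 1:3] <- norm$a_norm[, vx, ]
    out[, j + 4:12] <- matrix(norm$R_norm[, vx, , ], n, 9L)
    j <- j + 12L
  }
  out
}
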