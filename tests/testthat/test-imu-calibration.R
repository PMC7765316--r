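test_that("gravity cleaning matches the static pose and the matrix oracle", {
  cal <- calibration_state()
  g <- gravity_vector()

  # static pose: the reading is pure gravity, cleaned output is zero
  expect_equal(calibrate_acceleration(g, diag(3), cal), c(0, 0, 0))
  # an extra unit of x acceleration survives cleaning
  expect_equal(calibrate_acceleration(g + c(1, 0, 0), diag(3), cal), c(1, 0, 0))

  # rotated frames against the explicit two-step oracle
  Rz <- rot_z(pi / 2); Rx <- rot_x(pi / 2)
  calz <- calibration_state(R_calib = Rx)
  got <- calibrate_acceleration(c(1, 2, 3), Rz, calz)
  expect_equal(got, oracle_calibrate_acceleration(c(1, 2, 3), Rz, Rx, g),
               tolerance = 1e-14)

  set.seed(11)
  for (i in 1:50) {
    a <- rnorm(3, sd = 5)
    Ri <- random_rotation(); Rc <- random_rotation()
    cal_i <- calibration_state(R_calib = Rc)
    expect_equal(calibrate_acceleration(a, Ri, cal_i),
                 oracle_calibrate_acceleration(a, Ri, Rc, g),
                 tolerance = 1e-12)
  }
})

test_that("orientation localization composes the three rotations", {
  cal <- calibration_state()
  expect_equal(calibrate_orientation(diag(3), cal), diag(3))

  set.seed(12)
  Ri <- random_rotation()
  cal_inv <- calibration_state(R_calib = t(Ri))
  expect_equal(calibrate_orientation(Ri, cal_inv), diag(3), tolerance = 1e-12)

  for (i in 1:50) {
    Ri <- random_rotation(); Rc <- random_rotation(); Rb <- random_rotation()
    cal_i <- calibration_state(R_calib = Rc, R_bone = Rb)
    got <- calibrate_orientation(Ri, cal_i)
    expect_equal(got, oracle_calibrate_orientation(Ri, Rc, Rb),
                 tolerance = 1e-12)
    expect_true(is_rotation(got, tol = 1e-8))
  }
})

test_that("root normalization matches the explicit-inverse oracle", {
  # sensor identical to root: zero acceleration, identity orientation
  set.seed(13)
  Rr <- random_rotation(); ar <- rnorm(3)
  self <- normalize_to_root(ar, Rr, ar, Rr)
  expect_equal(self$a_normalized, c(0, 0, 0))
  expect_equal(self$R_normalized, diag(3), tolerance = 1e-12)

  # identity root reduces to a plain difference
  al <- rnorm(3); Rl <- random_rotation()
  id_root <- normalize_to_root(al, Rl, ar, diag(3))
  expect_equal(id_root$a_normalized, al - ar)

  for (i in 1:50) {
    al <- rnorm(3); ar <- rnorm(3)
    Rl <- random_rotation(); Rr <- random_rotation()
    got <- normalize_to_root(al, Rl, ar, Rr)
    want <- oracle_normalize_to_root(al, Rl, ar, Rr)
    expect_equal(got$a_normalized, want$a_normalized, tolerance = 1e-12)
    expect_equal(got$R_normalized, want$R_normalized, tolerance = 1e-12)
    expect_true(is_rotation(got$R_normalized, tol = 1e-8))
  }
})

test_that("calibration rejects non-orthonormal rotations", {
  bad <- diag(3); bad[1, 1] <- 2
  expect_error(calibration_state(R_calib = bad), "rotation")
  expect_error(calibrate_acceleration(c(0, 0, 0), bad, calibration_state()),
               "rotation")
  expect_error(normalize_to_root(c(0, 0, 0), diag(3), c(0, 0, 0), bad),
               "rotation")
})

test_that("localized pipeline is equivariant under a global frame rotation", {
  # rotating the world by Q while re-deriving the calibration from the same
  # physical pose leaves localized (and hence root-normalized) outputs
  # unchanged
  set.seed(14)
  for (i in 1:20) {
    Q <- random_rotation()
    R_pose <- random_rotation()          # sensor orientation at calibration
    R_imu <- random_rotation() %*% R_pose
    a_imu <- rnorm(3, sd = 3)
    g <- gravity_vector()

    cal <- calibration_from_pose(R_pose, g = g)
    a1 <- calibrate_acceleration(a_imu, R_imu, cal)
    R1 <- calibrate_orientation(R_imu, cal)

    cal_q <- calibration_from_pose(Q %*% R_pose, g = drop(Q %*% g))
    a2 <- calibrate_acceleration(a_imu, Q %*% R_imu, cal_q)
    R2 <- calibrate_orientation(Q %*% R_imu, cal_q)

    expect_equal(a1, a2, tolerance = 1e-10)
    expect_equal(R1, R2, tolerance = 1e-10)
  }
})

test_that("dead reckoning reproduces the closed-form double sum", {
  # zero acceleration, zero initial velocity: stays put
  x <- dead_reckon(matrix(0, 20, 3), dt = 0.1)
  expect_equal(x, matrix(0, 21, 3))

  # constant unit acceleration on z: x_N = dt^2 * N (N + 1) / 2
  x <- dead_reckon(matrix(c(0, 0, 1), 10, 3, byrow = TRUE), dt = 0.1)
  expect_equal(x[11, 3], 0.55, tolerance = 1e-12)
  N <- seq_len(10)
  expect_equal(x[-1, 3], 0.1^2 * N * (N + 1) / 2, tolerance = 1e-12)

  # empty series returns the initial state
  expect_equal(dead_reckon(matrix(0, 0, 3), dt = 0.1, x0 = c(1, 2, 3)),
               matrix(c(1, 2, 3), 1, 3))
})

test_that("constant-bias drift error grows quadratically in elapsed time", {
  a <- matrix(c(0.05, 0, 0), 1200, 3, byrow = TRUE)
  x <- dead_reckon(a, dt = 1 / 60)
  err <- sqrt(rowSums(x^2))
  # doubling the elapsed time quadruples the error
  expect_equal(err[1201] / err[601], 4, tolerance = 0.02)
  # fitted log-log slope of the drift law
  slope <- drift_loglog_slope(bias = c(0.1, 0, 0), dt = 1 / 60, n_steps = 600L)
  expect_gt(slope, 1.95)
  expect_lt(slope, 2.05)
})

test_that("calibration states round-trip through the CSV interface", {
  set.seed(15)
  cals <- list(head = calibration_state(random_rotation(), random_rotation()),
               root = calibration_state())
  path <- tempfile(fileext = ".csv")
  write_calibration_csv(cals, path)
  back <- read_calibration_csv(path)
  expect_named(back, c("head", "root"))
  expect_equal(back$head$R_calib, cals$head$R_calib, tolerance = 1e-12)
  expect_equal(back$head$R_bone, cals$head$R_bone, tolerance = 1e-12)
  expect_equal(back$root$R_calib, diag(3))
})
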