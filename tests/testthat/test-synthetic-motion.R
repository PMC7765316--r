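test_that("class trajectories are periodic, bounded and exact on the circle", {
  arch <- dip_activity_archetypes()
  expect_length(arch, 13L)
  expect_true(all(vapply(arch, `[[`, "", "motion_family") %in% motion_families()))
  # every family contributes at least one archetype
  expect_setequal(unique(unname(vapply(arch, `[[`, "", "motion_family"))),
                  motion_families())

  # periodicity: t = 0 and t = 1/f coincide for every archetype
  for (spec in arch) {
    p0 <- class_trajectory(spec, 0)
    p1 <- class_trajectory(spec, 1 / spec$frequency)
    expect_equal(p0, p1, tolerance = 1e-9)
  }

  # bounded range of the linear oscillation: within 2a box of rest
  spec <- arch[["arm_stretches_up"]]
  t <- seq(0, 10, by = 1 / 60)
  p <- class_trajectory(spec, t)
  rest <- class_trajectory(spec, 0)  # includes rest offsets
  for (v in seq_len(dim(p)[2])) {
    spread <- apply(p[, v, ], 2L, function(z) diff(range(z)))
    expect_true(all(spread <= 2 * spec$amplitude + 1e-9))
  }

  # circle radius: mean distance to center equals the radius exactly
  circ <- activity_spec("c", "planar-circle", amplitude = 0.3, frequency = 0.5,
                        vertex_weights = c(rwrist = 1))
  t <- seq(0, 2 - 1 / 60, by = 1 / 60)
  p <- class_trajectory(circ, t)
  ctr <- colMeans(p[, "rwrist", ])
  d <- sqrt(rowSums(sweep(p[, "rwrist", ], 2L, ctr, "-")^2))
  expect_equal(mean(d), 0.3, tolerance = 1e-9)

  expect_error(activity_spec("x", "wiggle", 1, 1), "motion_family")
  expect_error(activity_spec("x", "planar-circle", -1, 1))
})

test_that("cohort generation counts, determinism and noise calibration", {
  cfg <- cohort_config(n_subjects = 2L, classes = tiny_classes(),
                       duration_per_class = 10, seed = 42L)
  coh <- make_cohort(cfg)
  expect_length(coh, 6L)
  expect_true(all(vapply(coh, function(s) dim(s$positions)[1L], 0L) == 600L))
  expect_equal(cohort_subjects(coh), c("S01", "S02"))

  # bit-identical reruns
  coh2 <- make_cohort(cfg)
  expect_identical(lapply(coh, `[[`, "positions"),
                   lapply(coh2, `[[`, "positions"))

  # noise SD: difference between noisy and clean cohort has SD ~ noise_sd
  cfg0 <- cohort_config(n_subjects = 2L, classes = tiny_classes(),
                        duration_per_class = 60, noise_sd = 0, seed = 42L)
  cfg1 <- cohort_config(n_subjects = 2L, classes = tiny_classes(),
                        duration_per_class = 60, noise_sd = 0.01, seed = 42L)
  d <- unlist(Map(function(a, b) a$positions - b$positions,
                  make_cohort(cfg1), make_cohort(cfg0)))
  expect_gt(length(d), 1e4)
  expect_equal(sd(d), 0.01, tolerance = 0.02)
})

test_that("distinct motion families separate classes more than subjects", {
  cfg <- cohort_config(n_subjects = 3L, classes = tiny_classes(),
                       duration_per_class = 10, noise_sd = 0, seed = 9L)
  coh <- make_cohort(cfg)
  labs <- vapply(coh, `[[`, "", "label")
  flat <- lapply(coh, function(s) as.vector(s$positions))
  traj_dist <- function(i, j) sqrt(mean((flat[[i]] - flat[[j]])^2))
  within <- c(); between <- c()
  for (i in seq_along(coh)) for (j in seq_along(coh)) {
    if (i >= j) next
    if (labs[i] == labs[j]) within <- c(within, traj_dist(i, j))
    else between <- c(between, traj_dist(i, j))
  }
  expect_gt(mean(between), mean(within))
})

test_that("synthetic IMU readings are physically consistent", {
  # stationary body: the reported acceleration is exactly gravity
  still <- motion_sequence(array(0.5, dim = c(10L, 2L, 3L),
                                 dimnames = list(NULL, c("a", "b"), NULL)),
                           "S01", "still", 60)
  rec <- imu_from_trajectory(still)
  for (t in 1:10) for (v in 1:2) {
    expect_equal(rec$a[t, v, ], gravity_vector())
  }

  # uniform circular motion: magnitude ~ r * omega^2 with gravity zeroed
  r <- 0.3; f <- 0.5; omega <- 2 * pi * f
  circ <- activity_spec("c", "planar-circle", amplitude = r, frequency = f,
                        vertex_weights = c(rwrist = 1))
  t <- seq(0, 4, by = 1 / 240)
  pos <- class_trajectory(circ, t)
  seq_ <- motion_sequence(pos, "S01", "c", 240)
  rec <- imu_from_trajectory(seq_, gravity = c(0, 0, 0))
  mid <- 50:900
  mags <- sqrt(rowSums(rec$a[mid, 4, ]^2))  # rwrist is vertex 4
  expect_equal(mean(mags), r * omega^2, tolerance = 1e-3)

  expect_error(imu_from_trajectory(
    motion_sequence(array(0, c(2L, 1L, 3L)), "s", "l", 60)), "3 frames")
})

test_that("dead reckoning round-trips the synthetic IMU stream", {
  r <- 0.3; f <- 0.5
  circ <- activity_spec("c", "planar-circle", amplitude = r, frequency = f,
                        vertex_weights = c(rwrist = 1))
  roundtrip_error <- function(rate) {
    t <- seq(0, 2, by = 1 / rate)
    pos <- class_trajectory(circ, t)
    seq_ <- motion_sequence(pos, "S01", "c", rate)
    rec <- imu_from_trajectory(seq_)
    cal <- calibration_state()
    v <- 4L  # rwrist
    a_lin <- t(vapply(seq_along(t), function(k)
      calibrate_acceleration(rec$a[k, v, ], rec$R[k, v, , ], cal), numeric(3)))
    dt <- 1 / rate
    x0 <- pos[1L, v, ]
    v0 <- (pos[2L, v, ] - pos[1L, v, ]) / dt
    x <- dead_reckon(a_lin[-1L, , drop = FALSE], dt, x0 = x0, v0 = v0)
    n <- length(t)
    max(sqrt(rowSums((x[seq_len(n), ] - pos[, v, ])^2)))
  }
  e60 <- roundtrip_error(60)
  e120 <- roundtrip_error(120)
  # recovery is tight relative to the 0.3 m amplitude and shrinks with dt
  expect_lt(e60, 0.06)
  expect_lt(e120, e60 / 1.7)
})

test_that("velocity-tangent orientations are valid rotations and keep Eq-consistency", {
  circ <- activity_spec("c", "planar-circle", amplitude = 0.3, frequency = 0.5,
                        vertex_weights = c(rwrist = 1))
  t <- seq(0, 1, by = 1 / 60)
  seq_ <- motion_sequence(class_trajectory(circ, t), "S01", "c", 60)
  rec_id <- imu_from_trajectory(seq_)
  rec_vt <- imu_from_trajectory(seq_, orientation_model = "velocity-tangent")
  cal <- calibration_state()
  for (k in seq(2, 60, by = 7)) {
    R <- rec_vt$R[k, 4L, , ]
    expect_true(is_rotation(R, tol = 1e-8))
    # the globally expressed linear acceleration is frame-independent
    expect_equal(calibrate_acceleration(rec_vt$a[k, 4L, ], R, cal),
                 calibrate_acceleration(rec_id$a[k, 4L, ], diag(3), cal),
                 tolerance = 1e-9)
  }
})

test_that("cohort containers round-trip through disk with a readable manifest", {
  coh <- tiny_cohort(duration = 2)
  dir <- tempfile("cohort")
  write_cohort(coh, dir)
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), length(coh))
  expect_equal(man$frames, rep(120L, length(coh)))
  back <- read_cohort(dir)
  expect_identical(lapply(back, `[[`, "positions"),
                   lapply(coh, `[[`, "positions"))
  unlink(dir, recursive = TRUE)
})
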