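# Independent oracles and shared fixtures for the test suite. Oracles are
# written against the mathematical definitions, not against the package's
# implementation paths.

# explicit two-step matrix arithmetic for gravity cleaning, element by
# element (independent of %*%)
oracle_calibrate_acceleration <- function(a_imu, R_imu, R_calib, g) {
  a_nog <- numeric(3)
  for (i in 1:3) {
    s <- 0
    for (j in 1:3) s <- s + R_imu[i, j] * a_imu[j]
    a_nog[i] <- s - g[i]
  }
  out <- numeric(3)
  for (i in 1:3) {
    s <- 0
    for (j in 1:3) s <- s + R_calib[i, j] * a_nog[j]
    out[i] <- s
  }
  out
}

# element-wise triple product oracle for orientation localization
oracle_calibrate_orientation <- function(R_imu, R_calib, R_bone) {
  tmp <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    s <- 0
    for (k in 1:3) s <- s + R_imu[i, k] * R_bone[k, j]
    tmp[i, j] <- s
  }
  out <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    s <- 0
    for (k in 1:3) s <- s + R_calib[i, k] * tmp[k, j]
    out[i, j] <- s
  }
  out
}

# root normalization via an explicitly computed inverse (solve, not t())
oracle_normalize_to_root <- function(a_local, R_local, a_root, R_root) {
  Rinv <- solve(R_root)
  list(a_normalized = drop(Rinv %*% (a_local - a_root)),
       R_normalized = Rinv %*% R_local)
}

# exact supercover oracle: enumerate the parametric crossings of integer
# grid lines along each segment and read the pixel at each inter-crossing
# midpoint. Independent of the incremental DDA in the implementation.
oracle_raster_segments <- function(xy, height, width) {
  grid <- matrix(0L, height, width)
  clamp <- function(v, hi) pmin(pmax(v, 0L), hi - 1L)
  px <- function(x, y) {
    c(clamp(floor(x), width), clamp(floor(y), height))
  }
  n <- nrow(xy)
  if (n == 1L) {
    p <- px(xy[1, 1], xy[1, 2])
    grid[p[2] + 1L, p[1] + 1L] <- grid[p[2] + 1L, p[1] + 1L] + 1L
    return(grid)
  }
  for (s in seq_len(n - 1L)) {
    x0 <- xy[s, 1]; y0 <- xy[s, 2]; x1 <- xy[s + 1, 1]; y1 <- xy[s + 1, 2]
    ts <- c(0, 1)
    if (x1 != x0) {
      ks <- seq(ceiling(min(x0, x1)), floor(max(x0, x1)))
      ts <- c(ts, (ks - x0) / (x1 - x0))
    }
    if (y1 != y0) {
      ks <- seq(ceiling(min(y0, y1)), floor(max(y0, y1)))
      ts <- c(ts, (ks - y0) / (y1 - y0))
    }
    ts <- sort(unique(pmin(pmax(ts, 0), 1)))
    # crossings closer than the corner tolerance are one corner crossing
    if (length(ts) > 1L) ts <- ts[c(TRUE, diff(ts) > 1e-9)]
    seen <- matrix(NA_integer_, 0, 2)
    for (m in seq_len(length(ts) - 1L)) {
      tm <- (ts[m] + ts[m + 1L]) / 2
      p <- px(x0 + tm * (x1 - x0), y0 + tm * (y1 - y0))
      if (!any(seen[, 1] == p[1] & seen[, 2] == p[2])) {
        seen <- rbind(seen, p)
        grid[p[2] + 1L, p[1] + 1L] <- grid[p[2] + 1L, p[1] + 1L] + 1L
      }
    }
  }
  grid
}

# direct evaluation of the cross-entropy definition, no log-sum-exp
oracle_cross_entropy <- function(s, p) {
  -log(exp(s[p]) / sum(exp(s)))
}

# small cached cohort for pipeline tests (2 subjects x 3 classes, noiseless
# variant available)
tiny_classes <- function() {
  arch <- dip_activity_archetypes()
  arch[c("arm_circles", "arm_raises", "squats")]
}

tiny_cohort <- function(noise_sd = 0.005, n_subjects = 2L, duration = 10,
                        seed = 5L) {
  make_cohort(cohort_config(n_subjects = n_subjects, classes = tiny_classes(),
                            duration_per_class = duration,
                            noise_sd = noise_sd, seed = seed))
}
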