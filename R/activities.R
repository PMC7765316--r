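#' Tracked body points
#'
#' The six body points tracked by the pipeline: head, lower back (the body
#' root), both wrists and both knees — the sensor placement used for
#' six-IMU full-body activity capture.
#'
#' @return Character vector of the six vertex names, in canonical channel
#'   order.
#' @export
tracked_vertices <- function() {
  c("head", "root", "lwrist", "rwrist", "lknee", "rknee")
}

# rest position of each vertex (meters, z-up, standing subject)
vertex_rest_positions <- function() {
  rbind(
    head   = c(0.00,  0.00, 1.65),
    root   = c(0.00,  0.00, 1.00),
    lwrist = c(0.00,  0.25, 0.80),
    rwrist = c(0.00, -0.25, 0.80),
    lknee  = c(0.00,  0.12, 0.50),
    rknee  = c(0.00, -0.12, 0.50)
  )
}

# lateral side of each vertex (+1 left/center, -1 right); drives the
# antiphase family
vertex_sides <- function() {
  c(head = 1, root = 1, lwrist = 1, rwrist = -1, lknee = 1, rknee = -1)
}

#' Motion families of the synthetic generator
#'
#' @return Character vector of the five parametric motion families.
#' @export
motion_families <- function() {
  c("planar-circle", "linear-oscillation", "lateral-zigzag",
    "vertical-dip", "composite-antiphase")
}

#' Parametric specification of one activity class
#'
#' An activity archetype: a motion family (the canonical parametric curve),
#' an amplitude and frequency, a rotation of the canonical motion plane, and
#' per-vertex participation weights saying how strongly each tracked body
#' point takes part in the motion.
#'
#' @param name Activity label.
#' @param motion_family One of [motion_families()].
#' @param amplitude Peak displacement, meters; must be positive.
#' @param frequency Repetition rate, Hz; must be positive.
#' @param plane_orientation 3x3 rotation applied to the canonical motion
#'   plane (default identity).
#' @param vertex_weights Named numeric vector over [tracked_vertices()],
#'   each in `[0, 1]`.
#' @return An object of class `activity_spec`.
#' @export
activity_spec <- function(name, motion_family, amplitude, frequency,
                          plane_orientation = diag(3),
                          vertex_weights = NULL) {
  vs <- tracked_vertices()
  if (is.null(vertex_weights)) {
    vertex_weights <- stats::setNames(rep(1, length(vs)), vs)
  }
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!motion_family %in% motion_families()) {
    stop(sprintf("unknown motion_family '%s'", motion_family), call. = FALSE)
  }
  stopifnot(amplitude > 0, frequency > 0)
  assert_rotation(plane_orientation, "plane_orientation")
  w <- rep(0, length(vs)); names(w) <- vs
  stopifnot(!is.null(names(vertex_weights)),
            all(names(vertex_weights) %in% vs))
  w[names(vertex_weights)] <- vertex_weights
  if (any(w < 0 | w > 1)) stop("vertex_weights must lie in [0, 1]", call. = FALSE)
  structure(list(name = name, motion_family = motion_family,
                 amplitude = amplitude, frequency = frequency,
                 plane_orientation = plane_orientation, vertex_weights = w),
            class = "activity_spec")
}

#' @export
print.activity_spec <- function(x, ...) {
  cat(sprintf("<activity_spec> %s: %s, A=%.2f m, f=%.2f Hz\n", x$name,
              x$motion_family, x$amplitude, x$frequency))
  active <- names(x$vertex_weights)[x$vertex_weights > 0]
  cat("  active vertices:", paste(active, collapse = ", "), "\n")
  invisible(x)
}

#' The 13 built-in activity archetypes
#'
#' Parametric stand-ins for the 13 activity classes of a six-IMU full-body
#' cohort (arm chest crossings, arm circles, arm head crossings, arm raises,
#' arm stretches up, cross stepping, jumping jacks, leg raises, lunges, side
#' stepping, squats, sumo squats, walking). Each class is mapped onto one of
#' the five motion families with a vertex-participation pattern chosen so
#' that classes differ in which body points move and in the shape their
#' trajectories trace, mirroring how the real activities differ.
#'
#' @return Named list of 13 [activity_spec()] objects, in label order.
#' @export
dip_activity_archetypes <- function() {
  specs <- list(
    # arms sweep in horizontal arcs folding against the chest
    activity_spec("arm_chest_crossings", "vertical-dip", 0.40, 0.60,
                  plane_orientation = rot_y(pi / 2),
                  vertex_weights = c(lwrist = 1, rwrist = 1)),
    # wrists trace circles around the shoulder
    activity_spec("arm_circles", "planar-circle", 0.30, 0.50,
                  vertex_weights = c(lwrist = 1, rwrist = 1)),
    # hands arc up behind the head; the head recoils slightly
    activity_spec("arm_head_crossings", "vertical-dip", 0.45, 0.50,
                  vertex_weights = c(lwrist = 1, rwrist = 1, head = 0.25)),
    # one arm raised straight to shoulder height and lowered
    activity_spec("arm_raises", "linear-oscillation", 0.45, 0.40,
                  vertex_weights = c(rwrist = 1, lwrist = 0.05)),
    # both hands travel vertically between shoulders and full stretch
    activity_spec("arm_stretches_up", "linear-oscillation", 0.35, 0.45,
                  vertex_weights = c(lwrist = 1, rwrist = 1)),
    # sideways steps crossing in front: strong knee zigzag with bounce
    activity_spec("cross_stepping", "lateral-zigzag", 0.35, 0.70,
                  vertex_weights = c(lknee = 1, rknee = 1, root = 0.5)),
    # arms and legs spread in opposite lateral directions
    activity_spec("jumping_jacks", "composite-antiphase", 0.50, 0.80,
                  vertex_weights = c(lwrist = 1, rwrist = 1,
                                     lknee = 0.6, rknee = 0.6)),
    # one knee raised to hip height and lowered
    activity_spec("leg_raises", "linear-oscillation", 0.40, 0.45,
                  vertex_weights = c(rknee = 1, lknee = 0.05)),
    # one leg lunges forward, the trunk dips asymmetrically
    activity_spec("lunges", "vertical-dip", 0.40, 0.35,
                  vertex_weights = c(root = 0.6, rknee = 1, lknee = 0.15,
                                     head = 0.4)),
    # sideways steps, one foot catching up: shallower knee zigzag
    activity_spec("side_stepping", "lateral-zigzag", 0.35, 0.70,
                  vertex_weights = c(lknee = 0.45, rknee = 0.45, root = 0.35)),
    # whole body dips: head, trunk, knees and arms all arc down and up
    activity_spec("squats", "vertical-dip", 0.40, 0.40,
                  vertex_weights = c(head = 1, root = 1, lwrist = 0.35,
                                     rwrist = 0.35, lknee = 0.35, rknee = 0.35)),
    # like squats with wide-spread legs: knees participate strongly
    activity_spec("sumo_squats", "vertical-dip", 0.35, 0.40,
                  vertex_weights = c(head = 0.9, root = 0.9, lwrist = 0.15,
                                     rwrist = 0.15, lknee = 0.9, rknee = 0.9)),
    # antiphase knee swing with a small head bob
    activity_spec("walking", "composite-antiphase", 0.30, 0.90,
                  vertex_weights = c(lknee = 1, rknee = 1, head = 0.12))
  )
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

# triangle wave with period 2*pi, range [-1, 1], tri(0) = 0
triangle_wave <- function(u) 2 / pi * asin(sin(u))

# canonical displacement of one vertex at phase u (vector), before plane
# rotation; returns length(u) x 3 matrix
family_displacement <- function(family, u, A, w, side) {
  n <- length(u)
  out <- matrix(0, n, 3L)
  if (w <= 0) return(out)
  switch(family,
    "planar-circle" = {
      # circle in the x-z plane (sagittal arm circles)
      out[, 1L] <- w * A * cos(u)
      out[, 3L] <- w * A * sin(u)
    },
    "linear-oscillation" = {
      out[, 3L] <- w * A * sin(u)
    },
    "lateral-zigzag" = {
      # lateral triangle wave plus a per-step vertical bounce whose relative
      # height scales with participation, so weight changes the path shape
      out[, 2L] <- w * A * triangle_wave(u)
      out[, 3L] <- 0.25 * A * sqrt(w) * (1 - cos(2 * u)) / 2
    },
    "vertical-dip" = {
      # downward half-cosine dip with a forward sway: an arc whose aspect
      # ratio depends on the participation weight
      out[, 3L] <- -w * A * (1 - cos(u)) / 2
      out[, 1L] <- 0.4 * A * sqrt(w) * sin(u) / 2
    },
    "composite-antiphase" = {
      # left and right limbs oscillate laterally in opposite directions
      out[, 2L] <- side * w * A * sin(u)
    },
    stop(sprintf("unknown motion_family '%s'", family), call. = FALSE)
  )
  out
}

#' Evaluate an activity archetype at given times
#'
#' Deterministic parametric trajectory of all six tracked vertices for one
#' activity, one subject. Periodic families repeat with period
#' `1/spec$frequency`.
#'
#' @param spec An [activity_spec()].
#' @param t Numeric vector of times, seconds (each `>= 0`).
#' @param subject_params List with `amp_scale` (multiplicative amplitude
#'   scale) and `phase` (phase offset, radians); defaults to the canonical
#'   subject (`amp_scale = 1`, `phase = 0`).
#' @return Array `length(t) x 6 x 3` of positions, meters; vertex order
#'   [tracked_vertices()].
#' @export
class_trajectory <- function(spec, t,
                             subject_params = list(amp_scale = 1, phase = 0)) {
  stopifnot(inherits(spec, "activity_spec"), all(t >= 0), all(is.finite(t)))
  vs <- tracked_vertices()
  rest <- vertex_rest_positions()
  sides <- vertex_sides()
  u <- 2 * pi * spec$frequency * t + subject_params$phase
  A <- spec$amplitude * subject_params$amp_scale
  out <- array(0, dim = c(length(t), length(vs), 3L),
               dimnames = list(NULL, vs, c("x", "y", "z")))
  for (v in seq_along(vs)) {
    d <- family_displacement(spec$motion_family, u, A,
                             spec$vertex_weights[[v]], sides[[v]])
    d <- d %*% t(spec$plane_orientation)
    out[, v, ] <- sweep(d, 2L, rest[v, ], "+")
  }
  out
}
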