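#' Derive a child seed from a parent seed and stream labels
#'
#' Deterministic integer mixing so that each (subject, class, purpose) stream
#' gets its own reproducible seed below 2^31.
#'
#' @param seed Parent integer seed.
#' @param ... Further integer components identifying the stream.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(list(...)))
  h <- 0
  m <- 2147483647  # 2^31 - 1, prime
  for (p in parts) {
    h <- (h * 48271 + (as.numeric(p) %% m) + 11) %% m
  }
  as.integer(h)
}

# evaluate expr with a private RNG stream, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Configuration of a synthetic activity cohort
#'
#' Defaults emulate the structure of a six-IMU full-body activity dataset:
#' 10 subjects, the 13 built-in activity classes, 60 Hz sampling.
#'
#' @param n_subjects Number of subjects (at least 2, so leave-one-person-out
#'   evaluation is possible).
#' @param classes List of [activity_spec()] objects; default the 13
#'   archetypes of [dip_activity_archetypes()].
#' @param sampling_rate Sampling rate, Hz.
#' @param duration_per_class Seconds of recording per subject per class.
#' @param subject_variation Fractional between-subject variation: the SD of
#'   the lognormal amplitude scale drawn per subject (phase offsets are
#'   always uniform on `[0, 2*pi)`).
#' @param noise_sd Positional Gaussian noise SD, meters.
#' @param seed Integer seed; fully determines the cohort.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 10L,
                          classes = dip_activity_archetypes(),
                          sampling_rate = 60,
                          duration_per_class = 60,
                          subject_variation = 0.1,
                          noise_sd = 0.005,
                          seed = 1L) {
  stopifnot(n_subjects >= 2L, sampling_rate > 0, duration_per_class > 0,
            subject_variation >= 0, noise_sd >= 0, length(classes) >= 1L)
  stopifnot(all(vapply(classes, inherits, TRUE, "activity_spec")))
  labels <- vapply(classes, `[[`, "", "name")
  if (anyDuplicated(labels)) stop("class names must be unique", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects), classes = classes,
                 sampling_rate = sampling_rate,
                 duration_per_class = duration_per_class,
                 subject_variation = subject_variation,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_config")
}

#' A labeled vertex-trajectory recording
#'
#' @param positions `frames x vertices x 3` array of positions, meters.
#' @param subject_id Subject identifier.
#' @param label Activity label.
#' @param sampling_rate Hz.
#' @return An object of class `motion_sequence`.
#' @export
motion_sequence <- function(positions, subject_id, label, sampling_rate) {
  stopifnot(is.array(positions), length(dim(positions)) == 3L,
            dim(positions)[3L] == 3L, all(is.finite(positions)),
            sampling_rate > 0)
  structure(list(positions = positions, subject_id = subject_id,
                 label = label, sampling_rate = sampling_rate),
            class = "motion_sequence")
}

#' @export
print.motion_sequence <- function(x, ...) {
  d <- dim(x$positions)
  cat(sprintf("<motion_sequence> subject %s, '%s': %d frames x %d vertices @ %g Hz\n",
              x$subject_id, x$label, d[1L], d[2L], x$sampling_rate))
  invisible(x)
}

# per-subject variation draws, seeded by (seed, subject index)
subject_parameters <- function(config, subject_index, n_classes) {
  with_seed(derive_seed(config$seed, 7L, subject_index), {
    list(
      amp_scale = rlnorm(1L, meanlog = 0, sdlog = config$subject_variation),
      phases = runif(n_classes, 0, 2 * pi)
    )
  })
}

#' Generate a labeled synthetic cohort
#'
#' For every subject and every activity class, evaluates the class archetype
#' with subject-specific amplitude scale and phase, adds positional Gaussian
#' noise, and returns one [motion_sequence()] per (subject, class). The seed
#' fully determines the output: identical configs give bit-identical cohorts.
#'
#' @param config A [cohort_config()].
#' @return A list of `n_subjects * length(classes)` motion sequences, with
#'   attribute `config`.
#' @export
make_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n_frames <- round(config$duration_per_class * config$sampling_rate)
  t <- (seq_len(n_frames) - 1L) / config$sampling_rate
  nv <- length(tracked_vertices())
  out <- vector("list", config$n_subjects * length(config$classes))
  k <- 0L
  for (s in seq_len(config$n_subjects)) {
    sp <- subject_parameters(config, s, length(config$classes))
    sid <- sprintf("S%02d", s)
    for (ci in seq_along(config$classes)) {
      spec <- config$classes[[ci]]
      pos <- class_trajectory(spec, t,
                              list(amp_scale = sp$amp_scale,
                                   phase = sp$phases[ci]))
      if (config$noise_sd > 0) {
        noise <- with_seed(derive_seed(config$seed, 13L, s, ci),
                           array(rnorm(length(pos), 0, config$noise_sd),
                                 dim = dim(pos)))
        pos <- pos + noise
      }
      k <- k + 1L
      out[[k]] <- motion_sequence(pos, sid, spec$name, config$sampling_rate)
    }
  }
  attr(out, "config") <- config
  out
}

#' Cohort subject roster
#'
#' @param cohort A list of motion sequences.
#' @return Sorted character vector of unique subject IDs.
#' @export
cohort_subjects <- function(cohort) {
  sort(unique(vapply(cohort, `[[`, "", "subject_id")))
}

#' Write / read a cohort container
#'
#' Persists a cohort as one array container (`cohort.rds`) plus a sidecar CSV
#' manifest (`manifest.csv` with subject_id, label, frames, sampling rate) so
#' downstream tools can inspect contents without loading the arrays.
#'
#' @param cohort A cohort from [make_cohort()].
#' @param dir Output directory (created if missing).
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` returns the
#'   cohort list.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(cohort, file.path(dir, "cohort.rds"))
  man <- data.frame(
    subject_id = vapply(cohort, `[[`, "", "subject_id"),
    label = vapply(cohort, `[[`, "", "label"),
    frames = vapply(cohort, function(s) dim(s$positions)[1L], 0L),
    sampling_rate = vapply(cohort, `[[`, 0, "sampling_rate")
  )
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  readRDS(file.path(dir, "cohort.rds"))
}
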