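#' Windowing configuration
#'
#' @param window_frames Frames per window (>= 2). The defaults follow the
#'   classifier input sizes: 150 frames (2.5 s at 60 Hz) per heatmap
#'   sub-window, 300 frames (5 s) for raw-signal models.
#' @param stride_frames Step between window starts; defaults to
#'   `window_frames` (no overlap), must lie in `[1, window_frames]` so
#'   windows never skip frames.
#' @param vertices Ordered vertex names to track (default all six).
#' @return An object of class `window_config`.
#' @export
window_config <- function(window_frames = 150L,
                          stride_frames = window_frames,
                          vertices = tracked_vertices()) {
  window_frames <- as.integer(window_frames)
  stride_frames <- as.integer(stride_frames)
  stopifnot(window_frames >= 2L, stride_frames >= 1L,
            stride_frames <= window_frames, length(vertices) >= 1L)
  structure(list(window_frames = window_frames, stride_frames = stride_frames,
                 vertices = vertices),
            class = "window_config")
}

#' Slice a motion sequence into fixed-length windows
#'
#' Windows start at frames `1, 1 + stride, 1 + 2*stride, ...`; a sequence
#' shorter than one window yields an empty list. Each window carries its
#' source coordinates (subject, label, start frame).
#'
#' @param seq A [motion_sequence()].
#' @param cfg A [window_config()].
#' @return List of windows; each is a list with `positions`
#'   (`window_frames x n_vertices x 3`), `subject_id`, `label`,
#'   `start_frame`, `sampling_rate`.
#' @export
segment <- function(seq, cfg) {
  stopifnot(inherits(seq, "motion_sequence"), inherits(cfg, "window_config"))
  n <- dim(seq$positions)[1L]
  w <- cfg$window_frames
  if (n < w) return(list())
  starts <- seq.int(1L, n - w + 1L, by = cfg$stride_frames)
  vidx <- match(cfg$vertices, dimnames(seq$positions)[[2L]])
  if (anyNA(vidx)) vidx <- seq_len(dim(seq$positions)[2L])[seq_along(cfg$vertices)]
  lapply(starts, function(s) {
    list(positions = seq$positions[s:(s + w - 1L), vidx, , drop = FALSE],
         subject_id = seq$subject_id, label = seq$label,
         start_frame = s, sampling_rate = seq$sampling_rate)
  })
}

#' Flatten a 3D point window to 2D by PCA
#'
#' Centers the points and projects them onto the top two principal axes of
#' their sample covariance. Because body-point motion is often nearly planar
#' but the plane orientation is arbitrary, this recovers the in-plane shape
#' of the motion regardless of how the subject was oriented. The sign of
#' each axis is fixed deterministically: the loading with the largest
#' magnitude is made positive (ties broken toward the first coordinate), so
#' identical inputs always give bit-identical outputs.
#'
#' @param points_3d An `n x 3` matrix (or `n x 1 x 3` slice) of points,
#'   `n >= 3`.
#' @return An object of class `projected_window`: list with `points_2d`
#'   (`n x 2`), `basis` (`3 x 2`, orthonormal columns), `explained_variance`
#'   (length 2, descending), `eigenvalues` (all three covariance
#'   eigenvalues) and `constant` (`TRUE` for a degenerate all-identical
#'   window, whose 2D points are all zero).
#' @export
pca_project <- function(points_3d) {
  if (length(dim(points_3d)) == 3L) {
    points_3d <- matrix(points_3d, dim(points_3d)[1L], 3L)
  }
  stopifnot(is.matrix(points_3d), ncol(points_3d) == 3L,
            nrow(points_3d) >= 3L, all(is.finite(points_3d)))
  ctr <- colMeans(points_3d)
  X <- sweep(points_3d, 2L, ctr, "-")
  if (max(abs(X)) == 0) {
    return(structure(list(points_2d = matrix(0, nrow(points_3d), 2L),
                          basis = diag(3)[, 1:2],
                          explained_variance = c(0, 0),
                          eigenvalues = c(0, 0, 0), constant = TRUE),
                     class = "projected_window"))
  }
  S <- crossprod(X) / (nrow(X) - 1L)
  e <- eigen(S, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  B <- e$vectors[, 1:2, drop = FALSE]
  for (k in 1:2) {
    v <- B[, k]
    j <- which(abs(v) == max(abs(v)))[1L]
    if (v[j] < 0) B[, k] <- -v
  }
  structure(list(points_2d = X %*% B, basis = B,
                 explained_variance = ev[1:2], eigenvalues = ev,
                 constant = FALSE),
            class = "projected_window")
}

#' @export
print.projected_window <- function(x, ...) {
  cat(sprintf("<projected_window> %d points, explained variance %.3g / %.3g%s\n",
              nrow(x$points_2d), x$explained_variance[1L],
              x$explained_variance[2L],
              if (x$constant) " (constant)" else ""))
  invisible(x)
}
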