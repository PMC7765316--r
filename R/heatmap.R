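#' Raster configuration for crossing-count heatmaps
#'
#' @param height,width Raster size in pixels (default 64 x 64, the image
#'   classifier's input resolution).
#' @param padding_fraction Fraction of the data extent added as margin
#'   around the window's bounding box before mapping onto the raster.
#' @param line_mode `"segments"` counts, for every pixel, how many straight
#'   segments between consecutive trajectory points cross it;
#'   `"points"` bins the sample points themselves.
#' @param normalize `"max"` scales each grid to `[0, 1]` by its maximum;
#'   `"none"` keeps raw integer counts.
#' @return An object of class `raster_config`.
#' @export
raster_config <- function(height = 64L, width = 64L, padding_fraction = 0.05,
                          line_mode = c("segments", "points"),
                          normalize = c("max", "none")) {
  height <- as.integer(height); width <- as.integer(width)
  stopifnot(height >= 2L, width >= 2L, padding_fraction >= 0)
  structure(list(height = height, width = width,
                 padding_fraction = padding_fraction,
                 line_mode = match.arg(line_mode),
                 normalize = match.arg(normalize)),
            class = "raster_config")
}

# map 2D points into continuous raster coordinates: per-window bounding box,
# expanded by padding_fraction, then an isotropic (aspect-preserving) scale
# centered on the raster. Returns n x 2 matrix with x (col) in [0, width],
# y (row) in [0, height].
map_to_raster <- function(points_2d, cfg) {
  stopifnot(all(is.finite(points_2d)))
  x <- points_2d[, 1L]; y <- points_2d[, 2L]
  ex <- diff(range(x)); ey <- diff(range(y))
  cx <- mean(range(x)); cy <- mean(range(y))
  ex <- ex * (1 + 2 * cfg$padding_fraction)
  ey <- ey * (1 + 2 * cfg$padding_fraction)
  s <- suppressWarnings(min(cfg$width / ex, cfg$height / ey))
  if (!is.finite(s)) s <- 0  # all points identical: map to center
  cbind((x - cx) * s + cfg$width / 2,
        (y - cy) * s + cfg$height / 2)
}

#' Rasterize a 2D trajectory window into a crossing-count grid
#'
#' The window's bounding box (plus padding) is mapped isotropically onto the
#' raster; in `segments` mode every pixel crossed by each straight segment
#' between consecutive points is incremented once per segment, in `points`
#' mode each sample point increments its containing pixel. The maximum
#' coordinate maps into the last pixel, so the grid always captures the full
#' window.
#'
#' @param points_2d An `n x 2` matrix of planar points (`n >= 1`), or a
#'   [pca_project()] result.
#' @param cfg A [raster_config()].
#' @return Integer `height x width` matrix of crossing counts.
#' @export
rasterize <- function(points_2d, cfg = raster_config()) {
  if (inherits(points_2d, "projected_window")) points_2d <- points_2d$points_2d
  if (is.null(dim(points_2d))) points_2d <- matrix(points_2d, ncol = 2L)
  stopifnot(ncol(points_2d) == 2L, nrow(points_2d) >= 1L)
  if (!all(is.finite(points_2d))) {
    stop("non-finite coordinates in trajectory window", call. = FALSE)
  }
  rc <- map_to_raster(points_2d, cfg)
  if (cfg$line_mode == "segments") {
    grid <- raster_segments_cpp(rc, cfg$height, cfg$width)
  } else {
    col <- pmin(pmax(floor(rc[, 1L]), 0), cfg$width - 1L)
    row <- pmin(pmax(floor(rc[, 2L]), 0), cfg$height - 1L)
    grid <- matrix(tabulate(row * cfg$width + col + 1L,
                            nbins = cfg$height * cfg$width),
                   cfg$height, cfg$width, byrow = TRUE)
  }
  storage.mode(grid) <- "integer"
  grid
}

#' Normalize a count grid to `[0, 1]`
#'
#' `max` mode divides by the largest entry; an all-zero grid is returned
#' unchanged.
#'
#' @param grid Nonnegative numeric matrix.
#' @param mode `"max"` or `"none"`.
#' @return Numeric matrix with maximum 1 (if any count present).
#' @export
normalize_heatmap <- function(grid, mode = c("max", "none")) {
  mode <- match.arg(mode)
  stopifnot(all(grid >= 0))
  if (mode == "none") return(grid)
  m <- max(grid)
  if (m > 0) grid / m else grid
}

#' Build one heatmap image sample from a trajectory segment
#'
#' Splits a segment into `n_sub` consecutive sub-windows of
#' `win_cfg$window_frames` frames each; within every sub-window, each
#' tracked vertex's 3D trajectory is PCA-flattened to 2D and rasterized into
#' its own channel. The result is the `n_sub x channels x height x width`
#' tensor consumed by the image classifier (defaults: 4 x 6 x 64 x 64 from a
#' 600-frame segment).
#'
#' @param segment A window from [segment()] (list with `positions`), or a
#'   [motion_sequence()] whose full length is used.
#' @param win_cfg A [window_config()]; `window_frames` is the sub-window
#'   length.
#' @param raster_cfg A [raster_config()].
#' @param n_sub Number of consecutive sub-windows (the image-sequence
#'   length).
#' @param project_per_subwindow If `TRUE` (default) PCA is fit inside each
#'   sub-window; if `FALSE` one basis per vertex is fit on the whole segment
#'   and shared across its sub-windows.
#' @param shared_basis If `TRUE`, a single PCA basis per (sub-)window is fit
#'   on the pooled centered points of all vertices instead of one basis per
#'   vertex.
#' @return An object of class `heatmap_sample`: list with `tensor`
#'   (`n_sub x C x H x W`, nonnegative), `label`, `subject_id`,
#'   `start_frame`, `augmented = FALSE`.
#' @export
build_image_sample <- function(segment, win_cfg = window_config(),
                               raster_cfg = raster_config(), n_sub = 4L,
                               project_per_subwindow = TRUE,
                               shared_basis = FALSE) {
  pos <- if (inherits(segment, "motion_sequence")) segment$positions else segment$positions
  stopifnot(is.array(pos), length(dim(pos)) == 3L)
  need <- win_cfg$window_frames * n_sub
  if (dim(pos)[1L] < need) {
    stop(sprintf("segment has %d frames; %d required (%d sub-windows of %d frames)",
                 dim(pos)[1L], need, n_sub, win_cfg$window_frames),
         call. = FALSE)
  }
  nv <- dim(pos)[2L]
  tensor <- array(0, dim = c(n_sub, nv, raster_cfg$height, raster_cfg$width))

  project <- function(pts, basis = NULL) {
    if (!is.null(basis)) {
      ctr <- colMeans(pts)
      return(sweep(pts, 2L, ctr, "-") %*% basis)
    }
    pca_project(pts)$points_2d
  }

  whole_basis <- NULL
  if (!project_per_subwindow || shared_basis) {
    # precompute segment-level bases where requested
    whole_basis <- vector("list", nv)
    if (shared_basis) {
      pooled <- do.call(rbind, lapply(seq_len(nv), function(v) {
        p <- matrix(pos[, v, ], ncol = 3L)
        sweep(p, 2L, colMeans(p), "-")
      }))
      shared <- pca_project(pooled)$basis
      for (v in seq_len(nv)) whole_basis[[v]] <- shared
    } else {
      for (v in seq_len(nv)) {
        whole_basis[[v]] <- pca_project(matrix(pos[, v, ], ncol = 3L))$basis
      }
    }
  }

  for (s in seq_len(n_sub)) {
    rng <- ((s - 1L) * win_cfg$window_frames + 1L):(s * win_cfg$window_frames)
    sub_shared <- NULL
    if (project_per_subwindow && shared_basis) {
      pooled <- do.call(rbind, lapply(seq_len(nv), function(v) {
        p <- matrix(pos[rng, v, ], ncol = 3L)
        sweep(p, 2L, colMeans(p), "-")
      }))
      sub_shared <- pca_project(pooled)$basis
    }
    for (v in seq_len(nv)) {
      pts <- matrix(pos[rng, v, ], ncol = 3L)
      p2 <- if (!is.null(sub_shared)) project(pts, sub_shared)
            else if (project_per_subwindow) project(pts)
            else project(pts, whole_basis[[v]])
      grid <- rasterize(p2, raster_cfg)
      tensor[s, v, , ] <- normalize_heatmap(grid, raster_cfg$normalize)
    }
  }
  structure(list(tensor = tensor,
                 label = if (!is.null(segment$label)) segment$label else NA_character_,
                 subject_id = if (!is.null(segment$subject_id)) segment$subject_id else NA_character_,
                 start_frame = if (!is.null(segment$start_frame)) segment$start_frame else 1L,
                 augmented = FALSE),
            class = "heatmap_sample")
}

#' @export
print.heatmap_sample <- function(x, ...) {
  d <- dim(x$tensor)
  cat(sprintf("<heatmap_sample> %s/%s: tensor %d x %d x %d x %d%s\n",
              x$subject_id, x$label, d[1L], d[2L], d[3L], d[4L],
              if (isTRUE(x$augmented)) " (augmented)" else ""))
  invisible(x)
}

#' Build the heatmap image dataset of a cohort
#'
#' Segments every sequence into non-overlapping `n_sub * window_frames`
#' frame chunks and builds one [build_image_sample()] per chunk.
#'
#' @param cohort A cohort from [make_cohort()].
#' @inheritParams build_image_sample
#' @return List of `heatmap_sample` objects.
#' @export
build_heatmap_dataset <- function(cohort, win_cfg = window_config(),
                                  raster_cfg = raster_config(), n_sub = 4L,
                                  project_per_subwindow = TRUE,
                                  shared_basis = FALSE) {
  seg_cfg <- window_config(window_frames = win_cfg$window_frames * n_sub,
                           vertices = win_cfg$vertices)
  out <- list()
  for (seq_ in cohort) {
    for (w in segment(seq_, seg_cfg)) {
      out[[length(out) + 1L]] <-
        build_image_sample(w, win_cfg, raster_cfg, n_sub,
                           project_per_subwindow, shared_basis)
    }
  }
  out
}

#' Export a heatmap sample as grayscale PNGs
#'
#' Writes one 8-bit grayscale PNG per sub-window per channel, named
#' `<prefix>_t<sub>_c<channel>.png`, for visual inspection of the generated
#' trajectories.
#'
#' @param sample A `heatmap_sample`.
#' @param dir Output directory.
#' @param prefix File-name prefix (default `label_subject`).
#' @return Character vector of files written, invisibly.
#' @export
export_heatmap_png <- function(sample, dir, prefix = NULL) {
  stopifnot(inherits(sample, "heatmap_sample"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(prefix)) prefix <- paste0(sample$label, "_", sample$subject_id)
  d <- dim(sample$tensor)
  files <- character(0)
  for (s in seq_len(d[1L])) for (ch in seq_len(d[2L])) {
    img <- sample$tensor[s, ch, , ]
    if (max(img) > 0) img <- img / max(img)
    f <- file.path(dir, sprintf("%s_t%d_c%d.png", prefix, s, ch))
    png::writePNG(img, f)
    files <- c(files, f)
  }
  invisible(files)
}
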