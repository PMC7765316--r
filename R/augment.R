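#' Available heatmap augmentation operations
#'
#' Exact, label-preserving pixel permutations: horizontal / vertical flips
#' and quarter-turn rotations. Arbitrary-angle rotations are deliberately
#' not offered — they would interpolate and break the count semantics of the
#' grids.
#'
#' @return Character vector of operation names.
#' @export
augment_ops <- function() c("flip_h", "flip_v", "rot90", "rot180", "rot270")

#' Augmentation policy
#'
#' @param ops Subset of [augment_ops()] to draw from.
#' @param copies_per_sample Augmented copies generated per original sample
#'   (>= 0).
#' @param seed Integer seed for the op draws.
#' @return An object of class `augment_policy`.
#' @export
augment_policy <- function(ops = augment_ops(), copies_per_sample = 1L,
                           seed = 1L) {
  copies_per_sample <- as.integer(copies_per_sample)
  stopifnot(copies_per_sample >= 0L, all(ops %in% augment_ops()))
  if (copies_per_sample > 0L && length(ops) == 0L) {
    stop("ops must be non-empty when copies_per_sample > 0", call. = FALSE)
  }
  structure(list(ops = ops, copies_per_sample = copies_per_sample,
                 seed = as.integer(seed)),
            class = "augment_policy")
}

# apply a spatial op to one H x W grid; rot90 is counter-clockwise
apply_grid_op <- function(g, op) {
  switch(op,
    flip_h = g[, rev(seq_len(ncol(g))), drop = FALSE],
    flip_v = g[rev(seq_len(nrow(g))), , drop = FALSE],
    rot90  = t(g)[rev(seq_len(ncol(g))), , drop = FALSE],
    rot180 = g[rev(seq_len(nrow(g))), rev(seq_len(ncol(g))), drop = FALSE],
    rot270 = t(g)[, rev(seq_len(nrow(g))), drop = FALSE],
    stop(sprintf("unknown augmentation op '%s'", op), call. = FALSE)
  )
}

#' Apply one augmentation op to a heatmap sample
#'
#' The same spatial transform is applied to every sub-window and channel;
#' the label is unchanged and the tensor shape is preserved. Quarter-turn
#' rotations require a square raster.
#'
#' @param sample A `heatmap_sample`.
#' @param op One of [augment_ops()].
#' @return A new `heatmap_sample` with `augmented = TRUE`.
#' @export
transform_heatmap <- function(sample, op) {
  stopifnot(inherits(sample, "heatmap_sample"))
  d <- dim(sample$tensor)
  if (op %in% c("rot90", "rot270") && d[3L] != d[4L]) {
    stop("quarter-turn rotations require a square raster", call. = FALSE)
  }
  out <- sample
  for (s in seq_len(d[1L])) for (ch in seq_len(d[2L])) {
    out$tensor[s, ch, , ] <- apply_grid_op(sample$tensor[s, ch, , ], op)
  }
  out$augmented <- TRUE
  out
}

#' Enlarge a training set by seeded augmentation
#'
#' Keeps every original sample and appends `copies_per_sample` transformed
#' copies of each, with ops drawn from the policy by a seeded generator.
#' Augmented samples carry `augmented = TRUE` so evaluation can enforce that
#' they never enter a test fold.
#'
#' @param samples List of `heatmap_sample` objects (a training fold).
#' @param policy An [augment_policy()].
#' @return List of length `length(samples) * (1 + copies_per_sample)`.
#' @export
augment_dataset <- function(samples, policy = augment_policy()) {
  stopifnot(inherits(policy, "augment_policy"))
  if (policy$copies_per_sample == 0L) return(samples)
  out <- samples
  with_seed(policy$seed, {
    for (i in seq_along(samples)) {
      ops <- sample(policy$ops, policy$copies_per_sample, replace = TRUE)
      for (op in ops) {
        out[[length(out) + 1L]] <- transform_heatmap(samples[[i]], op)
      }
    }
  })
  out
}
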