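# Dataset containers: pack sample lists into dense arrays for the training
# loop. Class levels are the sorted unique labels, fixed at packing time.

#' Pack heatmap samples into a model dataset
#'
#' @param samples List of `heatmap_sample` objects with identical tensor
#'   shapes.
#' @param levels Class labels in index order; default sorted unique labels.
#' @return A `model_dataset`: list with `X` (`HW x C x T x N` array), `y`
#'   (integer class indices), `levels`, `subjects`, `augmented`, `shape`
#'   (`c(T, C, H, W)`), `kind_hint = "convlstm_image"`.
#' @export
image_dataset <- function(samples, levels = NULL) {
  stopifnot(length(samples) >= 1L,
            all(vapply(samples, inherits, TRUE, "heatmap_sample")))
  d <- dim(samples[[1L]]$tensor)  # (T, C, H, W)
  labs <- vapply(samples, `[[`, "", "label")
  if (is.null(levels)) levels <- sort(unique(labs))
  y <- match(labs, levels)
  stopifnot(!anyNA(y))
  HW <- d[3L] * d[4L]
  X <- array(0, dim = c(HW, d[2L], d[1L], length(samples)))
  for (i in seq_along(samples)) {
    tn <- samples[[i]]$tensor
    stopifnot(all(dim(tn) == d))
    X[, , , i] <- array(aperm(tn, c(3L, 4L, 2L, 1L)), c(HW, d[2L], d[1L]))
  }
  structure(list(X = X, y = y, levels = levels,
                 subjects = vapply(samples, `[[`, "", "subject_id"),
                 augmented = vapply(samples, function(s) isTRUE(s$augmented), TRUE),
                 shape = c(d[1L], d[2L], d[3L], d[4L]),
                 kind_hint = "convlstm_image", n = length(samples)),
            class = "model_dataset")
}

#' Build raw-signal windows from a cohort
#'
#' Synthesizes IMU readings for every sequence, calibrates and
#' root-normalizes them, stacks the per-frame features of the five non-root
#' sensors (3 acceleration components + 9 orientation entries each, 60
#' features in all) and slices them into fixed-length windows — the input of
#' the sequence classifiers (default 300 frames = 5 s at 60 Hz).
#'
#' @param cohort A cohort from [make_cohort()].
#' @param window_frames Window length in frames.
#' @param stride_frames Step between windows (default no overlap).
#' @param orientation_model Passed to [imu_from_trajectory()].
#' @return A `model_dataset` with `X` (`T x F x N`), `kind_hint =
#'   "sequence"`.
#' @export
build_signal_dataset <- function(cohort, window_frames = 300L,
                                 stride_frames = window_frames,
                                 orientation_model = "identity") {
  xs <- list(); labs <- character(0); subs <- character(0)
  for (seq_ in cohort) {
    rec <- imu_from_trajectory(seq_, orientation_model = orientation_model)
    feats <- signal_features(normalize_recording(rec))
    n <- nrow(feats)
    if (n < window_frames) next
    for (s in seq.int(1L, n - window_frames + 1L, by = stride_frames)) {
      xs[[length(xs) + 1L]] <- feats[s:(s + window_frames - 1L), , drop = FALSE]
      labs <- c(labs, seq_$label); subs <- c(subs, seq_$subject_id)
    }
  }
  stopifnot(length(xs) >= 1L)
  levels <- sort(unique(labs))
  Fn <- ncol(xs[[1L]])
  X <- array(0, dim = c(window_frames, Fn, length(xs)))
  for (i in seq_along(xs)) X[, , i] <- xs[[i]]
  structure(list(X = X, y = match(labs, levels), levels = levels,
                 subjects = subs, augmented = rep(FALSE, length(xs)),
                 shape = c(window_frames, Fn), kind_hint = "sequence",
                 n = length(xs)),
            class = "model_dataset")
}

#' @export
print.model_dataset <- function(x, ...) {
  cat(sprintf("<model_dataset> %d samples, shape (%s), %d classes, %d subjects\n",
              x$n, paste(x$shape, collapse = ", "), length(x$levels),
              length(unique(x$subjects))))
  invisible(x)
}

# subset a dataset by sample index
dataset_subset <- function(ds, idx) {
  out <- ds
  if (ds$kind_hint == "convlstm_image") {
    out$X <- ds$X[, , , idx, drop = FALSE]
  } else {
    out$X <- ds$X[, , idx, drop = FALSE]
  }
  out$y <- ds$y[idx]
  out$subjects <- ds$subjects[idx]
  out$augmented <- ds$augmented[idx]
  out$n <- length(idx)
  out
}

# model input for a batch of sample indices
batch_input <- function(ds, idx, kind) {
  B <- length(idx)
  if (kind == "convlstm_image") {
    Tn <- ds$shape[1L]; C <- ds$shape[2L]
    HW <- dim(ds$X)[1L]
    lapply(seq_len(Tn), function(t) {
      A <- ds$X[, , t, idx, drop = FALSE]
      dim(A) <- c(HW, C, B)
      M <- aperm(A, c(1L, 3L, 2L))
      dim(M) <- c(HW * B, C)
      M
    })
  } else if (kind == "convlstm_1d") {
    Tn <- ds$shape[1L]; L <- ds$shape[2L]
    lapply(seq_len(Tn), function(t) {
      A <- ds$X[t, , idx, drop = FALSE]       # (1, L, B)
      dim(A) <- c(L * B, 1L)
      A
    })
  } else {
    A <- ds$X[, , idx, drop = FALSE]          # (T, F, B)
    M <- aperm(A, c(3L, 1L, 2L))              # (B, T, F)
    dim(M) <- c(B * ds$shape[1L], ds$shape[2L])
    M
  }
}
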