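#' Leave-one-person-out fold plan
#'
#' One fold per subject: that subject is the test set, all others train.
#' Subjects are ordered by sorted ID, so the plan is deterministic.
#'
#' @param cohort A cohort list (or anything with `subject_id` fields), or a
#'   character vector of subject IDs.
#' @return An object of class `fold_plan`: list of folds, each with
#'   `test_subject` and `train_subjects`.
#' @export
lopo_folds <- function(cohort) {
  subjects <- if (is.character(cohort)) sort(unique(cohort))
              else cohort_subjects(cohort)
  if (length(subjects) < 2L) {
    stop("leave-one-person-out needs at least 2 subjects", call. = FALSE)
  }
  folds <- lapply(subjects, function(s) {
    list(test_subject = s, train_subjects = setdiff(subjects, s))
  })
  structure(list(folds = folds, subjects = subjects), class = "fold_plan")
}

#' Mean accuracy with a 95% interval half-width
#'
#' The half-width is the normal-approximation 95% interval over fold
#' accuracies: `1.96 * sd(acc) / sqrt(n_folds)`. With fewer than 2 folds the
#' half-width is undefined and reported as `NA`.
#'
#' @param per_fold_accuracy Numeric vector of fold accuracies in `[0, 1]`.
#' @return List with `mean` and `halfwidth`.
#' @export
accuracy_interval <- function(per_fold_accuracy) {
  stopifnot(all(per_fold_accuracy >= 0 & per_fold_accuracy <= 1))
  n <- length(per_fold_accuracy)
  list(mean = mean(per_fold_accuracy),
       halfwidth = if (n >= 2L) 1.96 * sd(per_fold_accuracy) / sqrt(n) else NA_real_)
}

#' Row-normalized confusion matrix
#'
#' Entry (i, j) is the fraction of true-class-i samples predicted as class
#' j. Classes with no samples keep an all-zero row and are flagged in the
#' `empty_rows` attribute rather than normalized.
#'
#' @param y_true,y_pred Integer class indices in `[1, C]`.
#' @param C Number of classes.
#' @param normalize Row-normalize (default `TRUE`).
#' @return `C x C` matrix; attribute `counts` holds the raw counts and
#'   `empty_rows` the indices of unpopulated rows.
#' @export
confusion_matrix <- function(y_true, y_pred, C, normalize = TRUE) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  stopifnot(all(y_true >= 1L & y_true <= C), all(y_pred >= 1L & y_pred <= C))
  cm <- matrix(0, C, C)
  for (k in seq_along(y_true)) {
    cm[y_true[k], y_pred[k]] <- cm[y_true[k], y_pred[k]] + 1
  }
  counts <- cm
  empty <- which(rowSums(cm) == 0)
  if (normalize) {
    rs <- rowSums(cm)
    rs[rs == 0] <- 1
    cm <- cm / rs
  }
  attr(cm, "counts") <- counts
  attr(cm, "empty_rows") <- empty
  cm
}

#' Leave-one-person-out evaluation of a classifier
#'
#' Runs the full protocol: for every subject, trains the requested
#' architecture on all other subjects (one of them held out, seeded, as the
#' early-stopping validation set), then tests on the left-out subject.
#' Augmentation, when given, is applied to training folds only; augmented
#' samples never reach validation or test data, which is asserted on sample
#' provenance. Accuracy is computed per window sample.
#'
#' @param cohort A cohort from [make_cohort()].
#' @param kind Model kind, see [model_config()].
#' @param win_cfg,raster_cfg,n_sub Image-pipeline settings (image kind).
#' @param window_frames Window length for the sequence kinds.
#' @param augment `NULL` or an [augment_policy()] (image kind only).
#' @param model_args Named list of [model_config()] overrides
#'   (e.g. `learning_rate`, `max_epochs`).
#' @param seed Integer seed controlling model init, validation-subject
#'   choice and augmentation.
#' @param verbose Print per-fold progress.
#' @return An object of class `eval_report`: per-fold accuracies, mean and
#'   95% half-width, row-normalized confusion matrix, class levels, seed and
#'   config hash.
#' @export
evaluate_lopo <- function(cohort, kind = "convlstm_image",
                          win_cfg = window_config(), raster_cfg = raster_config(),
                          n_sub = 4L, window_frames = 300L,
                          augment = NULL, model_args = list(),
                          seed = 1L, verbose = FALSE) {
  if (!is.null(augment) && kind != "convlstm_image") {
    stop("image augmentation applies to the image model only", call. = FALSE)
  }
  image_kind <- kind == "convlstm_image"
  if (image_kind) {
    samples <- build_heatmap_dataset(cohort, win_cfg, raster_cfg, n_sub)
    if (length(samples) == 0L) {
      stop(sprintf(paste0("no image samples: sequences are shorter than one ",
                          "segment (%d frames = %d sub-windows x %d frames); ",
                          "reduce window_frames or n_sub"),
                   win_cfg$window_frames * n_sub, n_sub, win_cfg$window_frames),
           call. = FALSE)
    }
    levels <- sort(unique(vapply(samples, `[[`, "", "label")))
    subj_of <- vapply(samples, `[[`, "", "subject_id")
    shape <- dim(samples[[1L]]$tensor)
    input_shape <- shape
  } else {
    ds_all <- build_signal_dataset(cohort, window_frames = window_frames)
    levels <- ds_all$levels
    subj_of <- ds_all$subjects
    input_shape <- ds_all$shape
  }
  plan <- lopo_folds(cohort)
  accs <- numeric(0)
  y_true_all <- integer(0); y_pred_all <- integer(0)
  fold_rows <- list()

  for (fi in seq_along(plan$folds)) {
    fold <- plan$folds[[fi]]
    if (length(fold$train_subjects) >= 2L) {
      # early-stopping validation: one randomly held-out training subject
      val_subject <- with_seed(derive_seed(seed, 301L, fi),
                               sample(fold$train_subjects, 1L))
      fit_subjects <- setdiff(fold$train_subjects, val_subject)
      fit_idx <- which(subj_of %in% fit_subjects)
      val_idx <- which(subj_of %in% val_subject)
    } else {
      # a single training subject (2-subject cohort): hold out a seeded
      # quarter of its samples for validation instead
      fit_subjects <- fold$train_subjects
      pool <- which(subj_of %in% fit_subjects)
      nval <- max(1L, length(pool) %/% 4L)
      val_idx <- with_seed(derive_seed(seed, 301L, fi),
                           sort(sample(pool, nval)))
      fit_idx <- setdiff(pool, val_idx)
    }
    stopifnot(!fold$test_subject %in% fit_subjects,
              length(fit_idx) > 0L, length(val_idx) > 0L,
              !any(fit_idx %in% val_idx))

    if (image_kind) {
      tr_samples <- samples[fit_idx]
      if (!is.null(augment)) {
        pol <- augment_policy(augment$ops, augment$copies_per_sample,
                              seed = derive_seed(augment$seed, 401L, fi))
        tr_samples <- augment_dataset(tr_samples, pol)
      }
      train_ds <- image_dataset(tr_samples, levels = levels)
      val_ds <- image_dataset(samples[val_idx], levels = levels)
      test_ds <- image_dataset(samples[subj_of %in% fold$test_subject],
                               levels = levels)
    } else {
      train_ds <- dataset_subset(ds_all, fit_idx)
      val_ds <- dataset_subset(ds_all, val_idx)
      test_ds <- dataset_subset(ds_all, which(subj_of %in% fold$test_subject))
    }
    stopifnot(!any(test_ds$augmented), !any(val_ds$augmented))

    cfg <- do.call(model_config, modifyList(
      list(kind = kind, n_classes = length(levels), input_shape = input_shape,
           seed = derive_seed(seed, 501L, fi)),
      model_args))
    model <- build_model(cfg)
    model <- train_model(model, train_ds, val_ds, verbose = FALSE)
    ev <- evaluate_model(model, test_ds)
    accs <- c(accs, ev$accuracy)
    y_true_all <- c(y_true_all, test_ds$y)
    y_pred_all <- c(y_pred_all, ev$pred)
    fold_rows[[fi]] <- data.frame(test_subject = fold$test_subject,
                                  accuracy = ev$accuracy, n_test = test_ds$n,
                                  epochs = nrow(model$log))
    if (verbose) {
      message(sprintf("fold %d/%d (test %s): accuracy %.3f (%d epochs)",
                      fi, length(plan$folds), fold$test_subject, ev$accuracy,
                      nrow(model$log)))
    }
  }
  ai <- accuracy_interval(accs)
  structure(list(per_fold = do.call(rbind, fold_rows),
                 per_fold_accuracy = accs,
                 mean_accuracy = ai$mean, interval_halfwidth = ai$halfwidth,
                 confusion = confusion_matrix(y_true_all, y_pred_all,
                                              length(levels)),
                 y_true = y_true_all, y_pred = y_pred_all,
                 levels = levels, kind = kind, seed = seed,
                 unit = "window sample",
                 config_hash = config_hash(list(kind, seed, input_shape,
                                                model_args))),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s, leave-one-person-out over %d folds\n",
              x$kind, length(x$per_fold_accuracy)))
  cat(sprintf("  accuracy per %s: %.4f (+/- %.4f; 1.96*SD/sqrt(n) over folds)\n",
              x$unit, x$mean_accuracy, x$interval_halfwidth))
  cat(sprintf("  seed %d, config %s\n", x$seed, x$config_hash))
  invisible(x)
}

#' Accuracy versus cohort size sweep
#'
#' For each requested subject count, repeatedly draws a seeded random subject
#' subset (without replacement), runs leave-one-person-out evaluation on the
#' sub-cohort for every model kind, and tabulates mean accuracy and interval
#' half-width — the scaling experiment relating cohort size to classifier
#' choice.
#'
#' @param cohort A cohort from [make_cohort()].
#' @param kinds Character vector of model kinds.
#' @param subject_counts Integer vector of cohort sizes to test; counts
#'   below 2 are skipped with a warning.
#' @param repetitions Subset draws per count.
#' @param seed Integer seed.
#' @param ... Passed to [evaluate_lopo()].
#' @return A tidy data.frame with columns `kind`, `n_subjects`, `rep`,
#'   `mean_accuracy`, `interval_halfwidth`.
#' @export
subject_sweep <- function(cohort, kinds = "convlstm_image",
                          subject_counts = c(2L, 4L), repetitions = 3L,
                          seed = 1L, ...) {
  subjects <- cohort_subjects(cohort)
  subj_of <- vapply(cohort, `[[`, "", "subject_id")
  rows <- list()
  for (n in subject_counts) {
    if (n < 2L) {
      warning(sprintf("skipping subject count %d (< 2)", n))
      next
    }
    stopifnot(n <= length(subjects))
    reps <- if (n == length(subjects)) 1L else repetitions
    for (r in seq_len(reps)) {
      chosen <- with_seed(derive_seed(seed, 601L, n, r),
                          sort(sample(subjects, n)))
      sub_cohort <- cohort[subj_of %in% chosen]
      attr(sub_cohort, "config") <- attr(cohort, "config")
      for (kind in kinds) {
        rep_ <- evaluate_lopo(sub_cohort, kind = kind,
                              seed = derive_seed(seed, 701L, n, r), ...)
        rows[[length(rows) + 1L]] <-
          data.frame(kind = kind, n_subjects = n, rep = r,
                     mean_accuracy = rep_$mean_accuracy,
                     interval_halfwidth = rep_$interval_halfwidth)
      }
    }
  }
  do.call(rbind, rows)
}

#' Plot a confusion matrix heatmap
#'
#' @param report An `eval_report` (or a confusion matrix).
#' @param file Optional PNG path; when `NULL` draws on the active device.
#' @return The confusion matrix, invisibly.
#' @export
plot_confusion <- function(report, file = NULL) {
  cm <- if (inherits(report, "eval_report")) report$confusion else report
  labs <- if (inherits(report, "eval_report")) report$levels
          else as.character(seq_len(nrow(cm)))
  if (!is.null(file)) {
    grDevices::png(file, width = 800, height = 800)
    on.exit(grDevices::dev.off())
  }
  C <- nrow(cm)
  graphics::image(seq_len(C), seq_len(C), t(cm[C:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "Blues 3", rev = TRUE),
                  axes = FALSE, xlab = "predicted", ylab = "true",
                  main = "Row-normalized confusion matrix")
  graphics::axis(1L, at = seq_len(C), labels = labs, las = 2, cex.axis = 0.7)
  graphics::axis(2L, at = seq_len(C), labels = rev(labs), las = 2, cex.axis = 0.7)
  invisible(cm)
}
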