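test_that("cross-entropy matches its printed closed forms and the direct oracle", {
  # equal scores over C classes: loss is log(C)
  expect_equal(unclass(categorical_cross_entropy(rep(0.7, 13), 5L)), log(13),
               tolerance = 1e-12)
  # two classes, scores (1, 0), target first: -log(e / (e + 1))
  expect_equal(unclass(categorical_cross_entropy(c(1, 0), 1L)),
               -log(exp(1) / (exp(1) + 1)), tolerance = 1e-12)
  expect_equal(unclass(categorical_cross_entropy(c(1, 0), 1L)), 0.31326169,
               tolerance = 1e-7)

  # loss vanishes monotonically as the target score grows
  ls <- vapply(c(2, 5, 10, 20), function(sp)
    unclass(categorical_cross_entropy(c(sp, 0, 0), 1L)), 0)
  expect_true(all(diff(ls) < 0))
  expect_lt(ls[4], 1e-8)

  # log-sum-exp evaluation equals the direct formula on random draws
  set.seed(51)
  for (i in 1:1000) {
    C <- sample(2:15, 1L)
    s <- rnorm(C, sd = 3)
    p <- sample(C, 1L)
    expect_equal(unclass(categorical_cross_entropy(s, p)),
                 oracle_cross_entropy(s, p), tolerance = 1e-10)
  }

  expect_error(categorical_cross_entropy(c(0, 0), 3L), "range")
})

test_that("softmax is shift invariant and normalized", {
  set.seed(52)
  s <- matrix(rnorm(30), 5, 6)
  p <- trajheat:::softmax_rows(s)
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-12)
  expect_equal(trajheat:::softmax_rows(s + 100), p, tolerance = 1e-6)
})

test_that("built models expose the documented input/output contracts", {
  cfg <- model_config("convlstm_image", n_classes = 13L,
                      input_shape = c(4L, 6L, 64L, 64L), seed = 3L)
  m <- build_model(cfg)
  expect_equal(ncol(m$params$out_W), 13L)
  expect_equal(nrow(m$params$cl1_Wx), 5L * 5L * 6L)  # 16 5x5 filters over 6 channels
  expect_equal(ncol(m$params$cl1_Wx), 4L * 16L)
  expect_equal(nrow(m$params$cl2_Wx), 3L * 3L * 16L) # 32 3x3 filters
  expect_equal(ncol(m$params$cl2_Wx), 4L * 32L)

  # forward pass on a small batch: probabilities sum to one
  ds <- list(X = array(runif(64 * 64 * 6 * 4 * 2), c(64 * 64, 6L, 4L, 2L)),
             y = c(1L, 2L), levels = letters[1:13], subjects = c("a", "b"),
             augmented = c(FALSE, FALSE), shape = c(4L, 6L, 64L, 64L),
             kind_hint = "convlstm_image", n = 2L)
  class(ds) <- "model_dataset"
  pr <- predict(m, ds)
  expect_equal(dim(pr$p), c(2L, 13L))
  expect_equal(rowSums(pr$p), c(1, 1), tolerance = 1e-6)

  # raw-signal model accepts a 300-step, 60-feature sequence
  cfg2 <- model_config("lstm_raw", n_classes = 13L, input_shape = c(300L, 60L),
                       seed = 3L)
  m2 <- build_model(cfg2)
  ds2 <- list(X = array(rnorm(300 * 60 * 2), c(300L, 60L, 2L)), y = c(1L, 2L),
              levels = letters[1:13], subjects = c("a", "b"),
              augmented = c(FALSE, FALSE), shape = c(300L, 60L),
              kind_hint = "sequence", n = 2L)
  class(ds2) <- "model_dataset"
  pr2 <- predict(m2, ds2)
  expect_equal(rowSums(pr2$p), c(1, 1), tolerance = 1e-6)

  expect_error(model_config("convlstm_image", n_classes = 13L,
                            input_shape = c(300L, 60L)), "4 entries")
})

test_that("analytic gradients match finite differences on a tiny ConvLSTM", {
  cfg <- model_config("convlstm_image", n_classes = 3L,
                      input_shape = c(2L, 2L, 6L, 6L),
                      conv_filters = list(c(3L, 3L), c(4L, 3L)),
                      dense_units = 5L, seed = 8L)
  m <- build_model(cfg)
  set.seed(53)
  B <- 2L
  Xb <- lapply(1:2, function(t) matrix(rnorm(36 * B * 2), 36 * B, 2L))
  y <- c(1L, 3L)
  fw <- trajheat:::model_forward(m, Xb, B, cache = TRUE)
  gr <- trajheat:::model_backward(m, trajheat:::cce_grad(fw$logits, y), fw)
  eps <- 1e-5
  for (pn in names(m$params)) {
    n <- length(m$params[[pn]])
    for (i in sample(n, min(3L, n))) {
      mp <- m; mp$params[[pn]][i] <- mp$params[[pn]][i] + eps
      lp <- unclass(categorical_cross_entropy(
        trajheat:::model_forward(mp, Xb, B, cache = FALSE)$logits, y))
      mm <- m; mm$params[[pn]][i] <- mm$params[[pn]][i] - eps
      lm <- unclass(categorical_cross_entropy(
        trajheat:::model_forward(mm, Xb, B, cache = FALSE)$logits, y))
      expect_equal(gr[[pn]][i], (lp - lm) / (2 * eps), tolerance = 1e-4)
    }
  }
})

test_that("training fits a separable toy problem and honors its contracts", {
  # two visually distinct archetypes, tiny rasters
  coh <- make_cohort(cohort_config(
    n_subjects = 3L, classes = dip_activity_archetypes()[c("arm_circles",
                                                           "arm_raises")],
    duration_per_class = 5, noise_sd = 0.002, seed = 6L))
  samples <- build_heatmap_dataset(coh, window_config(75L),
                                   raster_config(8, 8), n_sub = 2L)
  ds <- image_dataset(samples)
  tr <- image_dataset(samples[ds$subjects != "S03"], levels = ds$levels)
  va <- image_dataset(samples[ds$subjects == "S03"], levels = ds$levels)
  cfg <- model_config("convlstm_image", n_classes = 2L,
                      input_shape = c(2L, 6L, 8L, 8L),
                      conv_filters = list(c(6L, 5L), c(8L, 3L)),
                      dense_units = 16L, learning_rate = 5e-3,
                      max_epochs = 25L, early_stopping_patience = 25L,
                      batch_size = 4L, seed = 10L)
  m <- train_model(build_model(cfg), tr, va)
  expect_equal(evaluate_model(m, tr)$accuracy, 1.0)
  # loss trends downward over the first epochs
  expect_lt(mean(m$log$train_loss[4:6]), mean(m$log$train_loss[1:3]))
  expect_lte(nrow(m$log), cfg$max_epochs)

  # determinism: same seed, same data, same final loss
  m2 <- train_model(build_model(cfg), tr, va)
  expect_identical(m$log, m2$log)
  expect_identical(m$params, m2$params)

  # patience 0 stops at the first non-improving epoch
  cfg0 <- model_config("convlstm_image", n_classes = 2L,
                       input_shape = c(2L, 6L, 8L, 8L),
                       conv_filters = list(c(2L, 3L), c(2L, 3L)),
                       dense_units = 4L, learning_rate = 0.5,
                       max_epochs = 30L, early_stopping_patience = 0L,
                       batch_size = 4L, seed = 11L)
  m0 <- train_model(build_model(cfg0), tr, va)
  expect_lte(nrow(m0$log), 30L)
  if (nrow(m0$log) < 30L) {
    vl <- m0$log$val_loss
    expect_gte(vl[length(vl)], min(vl[-length(vl)]))
  }
})

test_that("prediction breaks ties toward the lowest class index and batches freely", {
  cfg <- model_config("convlstm_image", n_classes = 3L,
                      input_shape = c(2L, 1L, 4L, 4L),
                      conv_filters = list(c(2L, 3L), c(2L, 3L)),
                      dense_units = 4L, batch_size = 2L, seed = 12L)
  m <- build_model(cfg)
  # zero output layer: all classes tie at probability 1/3
  m$params$out_W[] <- 0; m$params$out_b[] <- 0
  ds <- list(X = array(runif(16 * 1 * 2 * 5), c(16L, 1L, 2L, 5L)),
             y = rep(1L, 5), levels = letters[1:3], subjects = rep("a", 5),
             augmented = rep(FALSE, 5), shape = c(2L, 1L, 4L, 4L),
             kind_hint = "convlstm_image", n = 5L)
  class(ds) <- "model_dataset"
  pr <- predict(m, ds)
  expect_true(all(pr$class_index == 1L))

  # batch invariance on a non-degenerate model
  m <- build_model(cfg)
  pr_all <- predict(m, ds)
  one_by_one <- vapply(1:5, function(i)
    predict(m, trajheat:::dataset_subset(ds, i))$class_index, 0L)
  expect_identical(pr_all$class_index, one_by_one)
  expect_equal(pr_all$s, do.call(rbind, lapply(1:5, function(i)
    predict(m, trajheat:::dataset_subset(ds, i))$s)), tolerance = 1e-10)
})
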