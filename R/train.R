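#' Train a classifier with Adam and early stopping
#'
#' Minibatch training with the Adam optimizer on the categorical
#' cross-entropy loss. After every epoch the validation loss is measured;
#' when it fails to improve for `early_stopping_patience` consecutive
#' epochs, training stops and the best-validation weights are restored.
#' Shuffling is seeded from the model config, so a fixed seed, fixed data
#' and single-threaded numerics reproduce the run exactly.
#'
#' @param model An untrained model from [build_model()].
#' @param train_ds Training `model_dataset` (see [image_dataset()],
#'   [build_signal_dataset()]).
#' @param val_ds Validation `model_dataset`, disjoint from `train_ds`.
#' @param verbose Print per-epoch progress.
#' @return The trained model; `model$log` is a data.frame with per-epoch
#'   `train_loss`, `val_loss`, `val_accuracy`.
#' @export
train_model <- function(model, train_ds, val_ds, verbose = FALSE) {
  stopifnot(inherits(model, "trajheat_model"),
            inherits(train_ds, "model_dataset"),
            inherits(val_ds, "model_dataset"))
  if (train_ds$n == 0L || val_ds$n == 0L) {
    stop("training and validation sets must be non-empty", call. = FALSE)
  }
  cfg <- model$cfg
  kind <- cfg$kind
  state <- adam_init(model$params)
  best_val <- Inf
  best_params <- model$params
  wait <- 0L
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0), val_accuracy = numeric(0))

  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- with_seed(derive_seed(cfg$seed, 101L, epoch), sample(train_ds$n))
    total <- 0; nseen <- 0L
    for (start in seq.int(1L, train_ds$n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, train_ds$n)]
      Xb <- batch_input(train_ds, idx, kind)
      fw <- model_forward(model, Xb, length(idx), cache = TRUE)
      yb <- train_ds$y[idx]
      loss <- unclass(categorical_cross_entropy(fw$logits, yb))
      grads <- model_backward(model, cce_grad(fw$logits, yb), fw)
      upd <- adam_step(model$params, grads, state, cfg$learning_rate)
      model$params <- upd$params
      state <- upd$state
      total <- total + loss * length(idx)
      nseen <- nseen + length(idx)
    }
    ev <- evaluate_model(model, val_ds)
    log <- rbind(log, data.frame(epoch = epoch, train_loss = total / nseen,
                                 val_loss = ev$loss, val_accuracy = ev$accuracy))
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f  acc %.3f",
                      epoch, total / nseen, ev$loss, ev$accuracy))
    }
    if (ev$loss < best_val - 1e-8) {
      best_val <- ev$loss
      best_params <- model$params
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait > cfg$early_stopping_patience) break
    }
  }
  model$params <- best_params
  model$log <- log
  model$class_levels <- train_ds$levels
  model
}

#' Loss and accuracy of a model on a dataset
#'
#' @param model A `trajheat_model`.
#' @param ds A `model_dataset`.
#' @return List with `loss`, `accuracy`, `pred` (predicted class indices).
#' @export
evaluate_model <- function(model, ds) {
  pr <- predict(model, ds)
  loss <- unclass(categorical_cross_entropy(pr$s, ds$y))
  list(loss = loss, accuracy = mean(pr$class_index == ds$y), pred = pr$class_index)
}

#' Predict activity classes
#'
#' Forward pass in minibatches; the predicted class is the arg-max
#' probability, ties broken toward the lowest class index. Predicting
#' sample-by-sample and as a batch give identical results.
#'
#' @param object A `trajheat_model`.
#' @param newdata A `model_dataset`, a list of `heatmap_sample` objects, or
#'   a single `heatmap_sample`.
#' @param ... Unused.
#' @return List with `class_index` (1-based), `label` (if class levels are
#'   known), `p` (probability matrix, rows sum to 1), `s` (raw scores).
#' @export
predict.trajheat_model <- function(object, newdata, ...) {
  if (inherits(newdata, "heatmap_sample")) newdata <- list(newdata)
  if (is.list(newdata) && !inherits(newdata, "model_dataset")) {
    newdata <- image_dataset(newdata, levels = object$class_levels %||%
                               sort(unique(vapply(newdata, `[[`, "", "label"))))
  }
  kind <- object$cfg$kind
  n <- newdata$n
  s <- matrix(0, n, object$cfg$n_classes)
  bs <- object$cfg$batch_size
  for (start in seq.int(1L, n, by = bs)) {
    idx <- start:min(start + bs - 1L, n)
    Xb <- batch_input(newdata, idx, kind)
    fw <- model_forward(object, Xb, length(idx), cache = FALSE)
    s[idx, ] <- fw$logits
  }
  p <- softmax_rows(s)
  cls <- max.col(p, ties.method = "first")
  list(class_index = cls,
       label = if (!is.null(object$class_levels)) object$class_levels[cls] else NULL,
       p = p, s = s)
}

# polynomial rolling hash over a serialized object; stable identifier for
# run configs (not cryptographic)
config_hash <- function(x) {
  raw <- as.integer(serialize(x, NULL, version = 2L))
  h <- 0
  for (b in raw) h <- (h * 131 + b + 1) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Save / load a trained model container
#'
#' Persists parameters, config, class levels, training log and a config
#' hash; the training log is additionally written as CSV next to the model
#' file.
#'
#' @param model A `trajheat_model`.
#' @param path Output `.rds` path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  obj <- list(cfg = model$cfg, params = model$params,
              class_levels = model$class_levels, log = model$log,
              config_hash = config_hash(model$cfg))
  saveRDS(obj, path)
  if (!is.null(model$log)) {
    utils::write.csv(model$log, sub("\\.rds$", "_log.csv", path),
                     row.names = FALSE)
  }
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  structure(list(cfg = obj$cfg, params = obj$params,
                 class_levels = obj$class_levels, log = obj$log,
                 env = new.env(parent = emptyenv())),
            class = "trajheat_model")
}
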