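#' Classifier configuration
#'
#' Three architectures classify activity windows: `lstm_raw` (two stacked
#' LSTM layers on the raw normalized sensor sequence, then a dense
#' interpretation layer), `convlstm_1d` (the same sequence read by
#' convolutional-LSTM layers with 1-D kernels over the feature axis) and
#' `convlstm_image` (two convolutional-LSTM layers — 16 5x5 filters then 32
#' 3x3 filters, each followed by 2x2 spatial max-pooling — over the heatmap
#' image sequence, then time-distributed flattening and dense layers). All
#' end in a dense softmax layer over the activity classes and train with
#' Adam under early stopping.
#'
#' @param kind One of `"lstm_raw"`, `"convlstm_1d"`, `"convlstm_image"`.
#' @param n_classes Number of activity classes (>= 2).
#' @param input_shape `c(T, features)` for `lstm_raw`; `c(T, length)` for
#'   `convlstm_1d`; `c(T, channels, height, width)` for `convlstm_image`.
#' @param conv_filters List of `(filters, kernel)` pairs for the two
#'   convolutional-recurrent layers.
#' @param pool_size Max-pooling factor (spatial only).
#' @param lstm_units Hidden widths of the two LSTM layers (`lstm_raw`).
#' @param dense_units Width of the dense interpretation layer.
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Upper bound on training epochs.
#' @param early_stopping_patience Epochs without validation-loss improvement
#'   before stopping; best-validation weights are restored.
#' @param seed Integer seed for parameter initialization and shuffling.
#' @return An object of class `model_config`.
#' @export
model_config <- function(kind = c("convlstm_image", "lstm_raw", "convlstm_1d"),
                         n_classes, input_shape,
                         conv_filters = list(c(16L, 5L), c(32L, 3L)),
                         pool_size = 2L,
                         lstm_units = c(100L, 100L),
                         dense_units = 100L,
                         learning_rate = 1e-3,
                         batch_size = 32L,
                         max_epochs = 100L,
                         early_stopping_patience = 10L,
                         seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(n_classes >= 2L)
  expected_len <- switch(kind, convlstm_image = 4L, 2L)
  if (length(input_shape) != expected_len) {
    stop(sprintf("input_shape for kind '%s' must have %d entries", kind,
                 expected_len), call. = FALSE)
  }
  structure(list(kind = kind, n_classes = as.integer(n_classes),
                 input_shape = as.integer(input_shape),
                 conv_filters = conv_filters, pool_size = as.integer(pool_size),
                 lstm_units = as.integer(lstm_units),
                 dense_units = as.integer(dense_units),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stopping_patience = as.integer(early_stopping_patience),
                 seed = as.integer(seed)),
            class = "model_config")
}

# pooled spatial sizes of the image/1d pipeline
conv_pipeline_dims <- function(cfg) {
  if (cfg$kind == "convlstm_image") {
    H <- cfg$input_shape[3L]; W <- cfg$input_shape[4L]; C <- cfg$input_shape[2L]
    k1 <- c(cfg$conv_filters[[1L]][2L], cfg$conv_filters[[1L]][2L])
    k2 <- c(cfg$conv_filters[[2L]][2L], cfg$conv_filters[[2L]][2L])
    p <- c(cfg$pool_size, cfg$pool_size)
  } else {
    H <- cfg$input_shape[2L]; W <- 1L; C <- 1L
    k1 <- c(cfg$conv_filters[[1L]][2L], 1L)
    k2 <- c(cfg$conv_filters[[2L]][2L], 1L)
    p <- c(cfg$pool_size, 1L)
  }
  F1 <- cfg$conv_filters[[1L]][1L]; F2 <- cfg$conv_filters[[2L]][1L]
  H2 <- H %/% p[1L]; W2 <- W %/% p[2L]
  H3 <- H2 %/% p[1L]; W3 <- W2 %/% p[2L]
  list(H = H, W = W, C = C, F1 = F1, F2 = F2, k1 = k1, k2 = k2, pool = p,
       H2 = H2, W2 = W2, H3 = H3, W3 = W3, D = H3 * W3 * F2)
}

#' Build an untrained classifier
#'
#' Allocates seeded (Glorot-uniform) parameters for the requested
#' architecture.
#'
#' @param cfg A [model_config()].
#' @return An object of class `trajheat_model`.
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  params <- with_seed(cfg$seed, {
    if (cfg$kind == "lstm_raw") {
      Fin <- cfg$input_shape[2L]
      U1 <- cfg$lstm_units[1L]; U2 <- cfg$lstm_units[2L]
      list(
        l1_Wx = glorot(Fin, 4L * U1, Fin + U1, U1),
        l1_Wh = glorot(U1, 4L * U1, Fin + U1, U1),
        l1_b = lstm_bias(U1),
        l2_Wx = glorot(U1, 4L * U2, U1 + U2, U2),
        l2_Wh = glorot(U2, 4L * U2, U1 + U2, U2),
        l2_b = lstm_bias(U2),
        d_W = glorot(U2, cfg$dense_units),
        d_b = numeric(cfg$dense_units),
        out_W = glorot(cfg$dense_units, cfg$n_classes),
        out_b = numeric(cfg$n_classes)
      )
    } else {
      dm <- conv_pipeline_dims(cfg)
      K1 <- prod(dm$k1); K2 <- prod(dm$k2)
      Tn <- cfg$input_shape[1L]
      top_in <- if (cfg$kind == "convlstm_image") Tn * cfg$dense_units
                else cfg$dense_units
      dense_in <- dm$D
      list(
        cl1_Wx = glorot(K1 * dm$C, 4L * dm$F1, K1 * dm$C + K1 * dm$F1, dm$F1),
        cl1_Wh = glorot(K1 * dm$F1, 4L * dm$F1, K1 * dm$C + K1 * dm$F1, dm$F1),
        cl1_b = lstm_bias(dm$F1),
        cl2_Wx = glorot(K2 * dm$F1, 4L * dm$F2, K2 * dm$F1 + K2 * dm$F2, dm$F2),
        cl2_Wh = glorot(K2 * dm$F2, 4L * dm$F2, K2 * dm$F1 + K2 * dm$F2, dm$F2),
        cl2_b = lstm_bias(dm$F2),
        d_W = glorot(dense_in, cfg$dense_units),
        d_b = numeric(cfg$dense_units),
        out_W = glorot(top_in, cfg$n_classes),
        out_b = numeric(cfg$n_classes)
      )
    }
  })
  structure(list(cfg = cfg, params = params, class_levels = NULL,
                 env = new.env(parent = emptyenv())),
            class = "trajheat_model")
}

#' @export
print.trajheat_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf("<trajheat_model> %s: %d classes, input (%s), %d parameters%s\n",
              x$cfg$kind, x$cfg$n_classes,
              paste(x$cfg$input_shape, collapse = ", "), np,
              if (is.null(x$class_levels)) " (untrained)" else ""))
  invisible(x)
}

# geometry (im2col / pooling index tables) for a given batch size, cached
# on the model environment
model_geoms <- function(model, B) {
  key <- as.character(B)
  if (!is.null(model$env$geoms[[key]])) return(model$env$geoms[[key]])
  cfg <- model$cfg
  dm <- conv_pipeline_dims(cfg)
  R1 <- conv_indices(dm$H, dm$W, dm$k1[1L], dm$k1[2L])
  R2 <- conv_indices(dm$H2, dm$W2, dm$k2[1L], dm$k2[2L])
  p1 <- pool_indices(dm$H, dm$W, dm$pool[1L], dm$pool[2L])
  p2 <- pool_indices(dm$H2, dm$W2, dm$pool[1L], dm$pool[2L])
  g <- list(
    dm = dm,
    g1 = list(RIDX = R1,
              VIDX_x = batch_gather_index(R1, B, dm$C),
              VIDX_h = batch_gather_index(R1, B, dm$F1)),
    g2 = list(RIDX = R2,
              VIDX_x = batch_gather_index(R2, B, dm$F1),
              VIDX_h = batch_gather_index(R2, B, dm$F2)),
    p1rows = pool_batch_rows(p1, dm$H * dm$W, B),
    p2rows = pool_batch_rows(p2, dm$H2 * dm$W2, B)
  )
  if (is.null(model$env$geoms)) model$env$geoms <- list()
  model$env$geoms[[key]] <- g
  g
}

relu <- function(x) (x > 0) * x

# forward pass of the conv kinds. Xlist: list over T of (HW*B, C) maps.
forward_conv <- function(model, Xlist, B, cache = TRUE) {
  cfg <- model$cfg; pp <- model$params
  g <- model_geoms(model, B)
  dm <- g$dm
  Tn <- length(Xlist)
  cl1 <- convlstm_forward(Xlist, pp$cl1_Wx, pp$cl1_Wh, pp$cl1_b, g$g1, B, cache)
  P1 <- vector("list", Tn); arg1 <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    mp <- maxpool_forward(cl1$H[[t]], g$p1rows)
    P1[[t]] <- mp$Y; arg1[[t]] <- mp$arg
  }
  cl2 <- convlstm_forward(P1, pp$cl2_Wx, pp$cl2_Wh, pp$cl2_b, g$g2, B, cache)
  P2 <- vector("list", Tn); arg2 <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    mp <- maxpool_forward(cl2$H[[t]], g$p2rows)
    P2[[t]] <- mp$Y; arg2[[t]] <- mp$arg
  }
  HW3 <- dm$H3 * dm$W3
  flatten_t <- function(M) {
    dim(M) <- c(HW3, B, dm$F2)
    matrix(aperm(M, c(2L, 1L, 3L)), B, dm$D)
  }
  if (cfg$kind == "convlstm_image") {
    Zall <- do.call(rbind, lapply(P2, flatten_t))        # (T*B, D), b fast
    A <- relu(sweep(Zall %*% pp$d_W, 2L, pp$d_b, "+"))   # (T*B, U)
    U <- cfg$dense_units
    Arr <- array(A, c(B, Tn, U))
    Fm <- matrix(aperm(Arr, c(1L, 3L, 2L)), B, U * Tn)   # (B, U*T), unit fast
  } else {
    Zall <- flatten_t(P2[[Tn]])                          # (B, D)
    A <- relu(sweep(Zall %*% pp$d_W, 2L, pp$d_b, "+"))
    Fm <- A
  }
  logits <- sweep(Fm %*% pp$out_W, 2L, pp$out_b, "+")
  list(logits = logits,
       cache = if (cache) list(cl1 = cl1$cache, cl2 = cl2$cache,
                               arg1 = arg1, arg2 = arg2, P1 = P1,
                               Zall = Zall, A = A, Fm = Fm, Tn = Tn, B = B)
              else NULL)
}

backward_conv <- function(model, dlogits, fw) {
  cfg <- model$cfg; pp <- model$params
  ca <- fw$cache
  B <- ca$B; Tn <- ca$Tn
  g <- model_geoms(model, B)
  dm <- g$dm
  HW3 <- dm$H3 * dm$W3
  U <- cfg$dense_units

  dout_W <- crossprod(ca$Fm, dlogits)
  dout_b <- colSums(dlogits)
  dFm <- dlogits %*% t(pp$out_W)

  unflatten_t <- function(dZ) {
    dZ <- array(dZ, c(B, HW3, dm$F2))
    M <- aperm(dZ, c(2L, 1L, 3L))
    dim(M) <- c(HW3 * B, dm$F2)
    M
  }

  dH2 <- vector("list", Tn)
  if (cfg$kind == "convlstm_image") {
    dArr <- array(dFm, c(B, U, Tn))
    dA <- matrix(aperm(dArr, c(1L, 3L, 2L)), B * Tn, U)
    dA <- dA * (ca$A > 0)
    dd_W <- crossprod(ca$Zall, dA)
    dd_b <- colSums(dA)
    dZall <- dA %*% t(pp$d_W)
    for (t in seq_len(Tn)) {
      dZt <- dZall[(t - 1L) * B + seq_len(B), , drop = FALSE]
      dP2 <- unflatten_t(dZt)
      dH2[[t]] <- maxpool_backward(dP2, ca$arg2[[t]], g$p2rows,
                                   dm$H2 * dm$W2 * B, dm$F2)
    }
  } else {
    dA <- dFm * (ca$A > 0)
    dd_W <- crossprod(ca$Zall, dA)
    dd_b <- colSums(dA)
    dZ <- dA %*% t(pp$d_W)
    zero <- matrix(0, dm$H2 * dm$W2 * B, dm$F2)
    for (t in seq_len(Tn)) dH2[[t]] <- zero
    dP2 <- unflatten_t(dZ)
    dH2[[Tn]] <- maxpool_backward(dP2, ca$arg2[[Tn]], g$p2rows,
                                  dm$H2 * dm$W2 * B, dm$F2)
  }

  b2 <- convlstm_backward(dH2, ca$cl2, pp$cl2_Wx, pp$cl2_Wh, g$g2, B,
                          need_dx = TRUE)
  dH1 <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    dH1[[t]] <- maxpool_backward(b2$dX[[t]], ca$arg1[[t]], g$p1rows,
                                 dm$H * dm$W * B, dm$F1)
  }
  b1 <- convlstm_backward(dH1, ca$cl1, pp$cl1_Wx, pp$cl1_Wh, g$g1, B,
                          need_dx = FALSE)

  list(cl1_Wx = b1$dWx, cl1_Wh = b1$dWh, cl1_b = b1$db,
       cl2_Wx = b2$dWx, cl2_Wh = b2$dWh, cl2_b = b2$db,
       d_W = dd_W, d_b = dd_b, out_W = dout_W, out_b = dout_b)
}

forward_lstm <- function(model, Xmat, B, cache = TRUE) {
  cfg <- model$cfg; pp <- model$params
  Tn <- cfg$input_shape[1L]
  l1 <- lstm_forward(Xmat, B, Tn, pp$l1_Wx, pp$l1_Wh, pp$l1_b, cache)
  l2 <- lstm_forward(l1$H, B, Tn, pp$l2_Wx, pp$l2_Wh, pp$l2_b, cache)
  hT <- l2$H[(Tn - 1L) * B + seq_len(B), , drop = FALSE]
  A <- relu(sweep(hT %*% pp$d_W, 2L, pp$d_b, "+"))
  logits <- sweep(A %*% pp$out_W, 2L, pp$out_b, "+")
  list(logits = logits,
       cache = if (cache) list(l1 = l1, l2 = l2, hT = hT, A = A,
                               Xmat = Xmat, B = B, Tn = Tn)
              else NULL)
}

backward_lstm <- function(model, dlogits, fw) {
  pp <- model$params
  ca <- fw$cache
  B <- ca$B; Tn <- ca$Tn
  dout_W <- crossprod(ca$A, dlogits)
  dout_b <- colSums(dlogits)
  dA <- dlogits %*% t(pp$out_W)
  dA <- dA * (ca$A > 0)
  dd_W <- crossprod(ca$hT, dA)
  dd_b <- colSums(dA)
  dhT <- dA %*% t(pp$d_W)
  dH2 <- matrix(0, B * Tn, ncol(ca$l2$H))
  dH2[(Tn - 1L) * B + seq_len(B), ] <- dhT
  b2 <- lstm_backward(dH2, ca$l2$cache, ca$l1$H, B, Tn, pp$l2_Wx, pp$l2_Wh,
                      need_dx = TRUE)
  b1 <- lstm_backward(b2$dX, ca$l1$cache, ca$Xmat, B, Tn, pp$l1_Wx, pp$l1_Wh,
                      need_dx = FALSE)
  list(l1_Wx = b1$dWx, l1_Wh = b1$dWh, l1_b = b1$db,
       l2_Wx = b2$dWx, l2_Wh = b2$dWh, l2_b = b2$db,
       d_W = dd_W, d_b = dd_b, out_W = dout_W, out_b = dout_b)
}

model_forward <- function(model, Xb, B, cache = TRUE) {
  if (model$cfg$kind == "lstm_raw") forward_lstm(model, Xb, B, cache)
  else forward_conv(model, Xb, B, cache)
}

model_backward <- function(model, dlogits, fw) {
  if (model$cfg$kind == "lstm_raw") backward_lstm(model, dlogits, fw)
  else backward_conv(model, dlogits, fw)
}
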