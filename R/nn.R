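# Neural-network primitives: im2col convolution machinery, LSTM / ConvLSTM
# cells, pooling, dense layers, softmax cross-entropy and Adam. Everything
# runs on BLAS matrix products; feature maps are stored as matrices of shape
# (n_pixels * batch, channels) with the pixel index fastest.

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- im2col ----------------------------------------------------------------

# spatial neighbor table for a kh x kw 'same' convolution on an H x W grid:
# RIDX[p, k] = linear pixel index of the k-th kernel tap for output pixel p,
# or 0 where the tap falls outside the grid. Pixels are column-major (row
# index fastest), kernel taps ordered (dh fast, dw slow).
conv_indices <- function(H, W, kh, kw) {
  ch <- (kh - 1L) %/% 2L; cw <- (kw - 1L) %/% 2L
  i <- rep(seq_len(H), W)        # row of each pixel
  j <- rep(seq_len(W), each = H) # col
  RIDX <- matrix(0L, H * W, kh * kw)
  k <- 0L
  for (dw in seq_len(kw) - 1L - cw) for (dh in seq_len(kh) - 1L - ch) {
    k <- k + 1L
    ii <- i + dh; jj <- j + dw
    ok <- ii >= 1L & ii <= H & jj >= 1L & jj <= W
    RIDX[ok, k] <- ii[ok] + (jj[ok] - 1L) * H
  }
  RIDX
}

# batch gather index: VIDX[(p,b), (k,c)] = element index into the padded
# flat input vector c(M, pad-zeros) where M is (HW*B, C). Built once per
# (geometry, batch size) and cached by the caller.
batch_gather_index <- function(RIDX, B, C) {
  HW <- nrow(RIDX); K <- ncol(RIDX)
  pad_row <- HW * B + 1L  # rows beyond HW*B hold zeros
  FIDX <- matrix(pad_row, HW * B, K)
  off <- rep((seq_len(B) - 1L) * HW, each = HW)
  for (k in seq_len(K)) {
    col <- rep(RIDX[, k], B)
    ok <- col > 0L
    FIDX[ok, k] <- col[ok] + off[ok]
  }
  # expand over channels: column order k fast, c slow; stride between
  # channels in the padded flat vector is HW*B + 1
  stride <- HW * B + 1L
  VIDX <- matrix(0L, HW * B, K * C)
  for (c in seq_len(C)) {
    VIDX[, (c - 1L) * K + seq_len(K)] <- FIDX + (c - 1L) * stride
  }
  VIDX
}

# gather: M is (HW*B, C) -> col (HW*B, K*C)
im2col <- function(M, VIDX, K, C) {
  HWB <- nrow(M)
  Mpad <- rbind(M, matrix(0, 1L, C))
  matrix(Mpad[VIDX], HWB, K * C)
}

# scatter-add transpose of im2col: dcol (HW*B, K*C) -> dM (HW*B, C).
# Loops over kernel taps; within one tap every output row maps to a
# distinct input row, so vectorized indexed addition is exact.
col2im <- function(dcol, RIDX, B, C) {
  HW <- nrow(RIDX); K <- ncol(RIDX)
  dM <- matrix(0, HW * B, C)
  off <- rep((seq_len(B) - 1L) * HW, each = HW)
  for (k in seq_len(K)) {
    src <- RIDX[, k]
    ok <- src > 0L
    rows <- rep(src, B)[rep(ok, B)] + off[rep(ok, B)]
    cols <- (seq_len(C) - 1L) * K + k
    dM[rows, ] <- dM[rows, ] + dcol[rep(ok, B), cols, drop = FALSE]
  }
  dM
}

# ---- pooling ---------------------------------------------------------------

# index sets for (ph x pw) max pooling on an H x W grid (truncating ragged
# edges): a list of ph*pw vectors, sel[[k]][q] = input pixel feeding output
# pixel q via tap k
pool_indices <- function(H, W, ph, pw) {
  H2 <- H %/% ph; W2 <- W %/% pw
  i2 <- rep(seq_len(H2), W2); j2 <- rep(seq_len(W2), each = H2)
  sel <- list()
  for (dw in seq_len(pw) - 1L) for (dh in seq_len(ph) - 1L) {
    ii <- (i2 - 1L) * ph + 1L + dh
    jj <- (j2 - 1L) * pw + 1L + dw
    sel[[length(sel) + 1L]] <- ii + (jj - 1L) * H
  }
  list(sel = sel, H2 = H2, W2 = W2)
}

# expand pooling tap indices to a batch: input rows in (HW*B), output (H2W2*B)
pool_batch_rows <- function(pi, HW, B) {
  lapply(pi$sel, function(s) {
    as.vector(outer(s, (seq_len(B) - 1L) * HW, "+"))
  })
}

# max pool forward: M (HW*B, F) -> list(Y (H2W2*B, F), arg (tap index per cell))
maxpool_forward <- function(M, rows) {
  Y <- M[rows[[1L]], , drop = FALSE]
  arg <- matrix(1L, nrow(Y), ncol(Y))
  for (k in seq_along(rows)[-1L]) {
    Sk <- M[rows[[k]], , drop = FALSE]
    upd <- Sk > Y
    Y[upd] <- Sk[upd]
    arg[upd] <- k
  }
  list(Y = Y, arg = arg)
}

maxpool_backward <- function(dY, arg, rows, HWB, F_) {
  dM <- matrix(0, HWB, F_)
  for (k in seq_along(rows)) {
    mask <- arg == k
    if (!any(mask)) next
    dk <- dY * mask
    dM[rows[[k]], ] <- dM[rows[[k]], ] + dk
  }
  dM
}

# ---- losses ----------------------------------------------------------------

#' Categorical cross-entropy from raw scores
#'
#' Numerically stable (log-sum-exp) evaluation of the multi-class
#' cross-entropy `L = -log(exp(s_p) / sum_j exp(s_j))` for the target class
#' `p`. With all scores equal over `C` classes the loss is `log(C)`.
#'
#' @param s Numeric score vector (pre-softmax), or a matrix with one row per
#'   sample.
#' @param target_class 1-based target class index (vector for a matrix `s`).
#' @return Mean loss over samples, in nats (class `loss_value`: a
#'   nonnegative scalar).
#' @export
categorical_cross_entropy <- function(s, target_class) {
  if (is.null(dim(s))) s <- matrix(s, 1L)
  stopifnot(all(is.finite(s)), length(target_class) == nrow(s))
  if (any(target_class < 1L | target_class > ncol(s))) {
    stop("target class index out of range", call. = FALSE)
  }
  m <- apply(s, 1L, max)
  lse <- m + log(rowSums(exp(s - m)))
  sp <- s[cbind(seq_len(nrow(s)), target_class)]
  structure(mean(lse - sp), class = "loss_value")
}

#' @export
print.loss_value <- function(x, ...) {
  cat(sprintf("<loss> %.6f nats\n", unclass(x)))
  invisible(x)
}

# row-wise softmax of a score matrix
softmax_rows <- function(s) {
  m <- apply(s, 1L, max)
  e <- exp(s - m)
  e / rowSums(e)
}

# softmax + CCE gradient wrt scores (mean reduction): (p - onehot)/n
cce_grad <- function(s, target_class) {
  p <- softmax_rows(s)
  n <- nrow(s)
  p[cbind(seq_len(n), target_class)] <- p[cbind(seq_len(n), target_class)] - 1
  p / n
}

# ---- parameter init and Adam ----------------------------------------------

glorot <- function(nr, nc, fan_in = nr, fan_out = nc) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

# LSTM-style bias: forget gate initialized to 1 (gate order i, f, o, g)
lstm_bias <- function(F_) {
  b <- numeric(4L * F_)
  b[F_ + seq_len(F_)] <- 1
  b
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# ---- recurrent cells -------------------------------------------------------

# one ConvLSTM/LSTM gate nonlinearity pass: G (N, 4F) -> gates
split_gates <- function(G, F_) {
  list(i = sigmoid(G[, seq_len(F_), drop = FALSE]),
       f = sigmoid(G[, F_ + seq_len(F_), drop = FALSE]),
       o = sigmoid(G[, 2L * F_ + seq_len(F_), drop = FALSE]),
       g = tanh(G[, 3L * F_ + seq_len(F_), drop = FALSE]))
}

# backward through the gate nonlinearities; returns dG (N, 4F) and dc_prev
gate_backward <- function(dh, dc_next, gates, c_prev, c_t) {
  tc <- tanh(c_t)
  do_ <- dh * tc
  dc <- dc_next + dh * gates$o * (1 - tc^2)
  di <- dc * gates$g
  dg <- dc * gates$i
  df <- dc * c_prev
  dc_prev <- dc * gates$f
  dG <- cbind(di * gates$i * (1 - gates$i),
              df * gates$f * (1 - gates$f),
              do_ * gates$o * (1 - gates$o),
              dg * (1 - gates$g^2))
  list(dG = dG, dc_prev = dc_prev)
}

# ConvLSTM layer forward over a sequence.
# X: list over T of (HW*B, C) map matrices. Returns hidden sequence and cache.
convlstm_forward <- function(X, Wx, Wh, b, geom, B, cache = TRUE) {
  Tn <- length(X)
  HW <- nrow(geom$RIDX)
  F_ <- length(b) %/% 4L
  C <- ncol(X[[1L]])
  K <- ncol(geom$RIDX)
  h <- matrix(0, HW * B, F_)
  cc <- matrix(0, HW * B, F_)
  Hs <- vector("list", Tn)
  caches <- if (cache) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    colX <- im2col(X[[t]], geom$VIDX_x, K, C)
    colH <- im2col(h, geom$VIDX_h, K, F_)
    G <- colX %*% Wx + colH %*% Wh
    G <- sweep(G, 2L, b, "+")
    gt <- split_gates(G, F_)
    c_prev <- cc
    cc <- gt$f * c_prev + gt$i * gt$g
    h <- gt$o * tanh(cc)
    Hs[[t]] <- h
    if (cache) caches[[t]] <- list(colX = colX, colH = colH, gates = gt,
                                   c_prev = c_prev, c_t = cc)
  }
  list(H = Hs, cache = caches)
}

# ConvLSTM backward. dH: list over T of upstream gradients on each hidden
# output (zero matrices where unused). Returns weight grads and dX list.
convlstm_backward <- function(dH, cache, Wx, Wh, geom, B, need_dx = TRUE) {
  Tn <- length(dH)
  HW <- nrow(geom$RIDX)
  F_ <- ncol(dH[[Tn]])
  K <- ncol(geom$RIDX)
  C <- ncol(cache[[1L]]$colX) %/% K
  dWx <- matrix(0, nrow(Wx), ncol(Wx))
  dWh <- matrix(0, nrow(Wh), ncol(Wh))
  db <- numeric(4L * F_)
  dX <- if (need_dx) vector("list", Tn) else NULL
  dh_rec <- matrix(0, HW * B, F_)
  dc <- matrix(0, HW * B, F_)
  for (t in rev(seq_len(Tn))) {
    ca <- cache[[t]]
    dh <- dH[[t]] + dh_rec
    gb <- gate_backward(dh, dc, ca$gates, ca$c_prev, ca$c_t)
    dc <- gb$dc_prev
    dWx <- dWx + crossprod(ca$colX, gb$dG)
    dWh <- dWh + crossprod(ca$colH, gb$dG)
    db <- db + colSums(gb$dG)
    dcolH <- gb$dG %*% t(Wh)
    dh_rec <- col2im(dcolH, geom$RIDX, B, F_)
    if (need_dx) {
      dcolX <- gb$dG %*% t(Wx)
      dX[[t]] <- col2im(dcolX, geom$RIDX, B, C)
    }
  }
  list(dWx = dWx, dWh = dWh, db = db, dX = dX)
}

# plain LSTM forward over (B*T, Fin) input (rows: batch fastest).
# Returns hidden state sequence matrix (B*T, H) and cache.
lstm_forward <- function(Xmat, B, Tn, Wx, Wh, b, cache = TRUE) {
  nh <- nrow(Wh)  # hidden width; Wh is (H, 4H)
  Gx <- Xmat %*% Wx  # (B*T, 4H)
  h <- matrix(0, B, nh)
  cc <- matrix(0, B, nh)
  Hs <- matrix(0, B * Tn, nh)
  caches <- if (cache) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    rows <- (t - 1L) * B + seq_len(B)
    G <- Gx[rows, , drop = FALSE] + h %*% Wh
    G <- sweep(G, 2L, b, "+")
    gt <- split_gates(G, nh)
    c_prev <- cc
    cc <- gt$f * c_prev + gt$i * gt$g
    h_prev <- h
    h <- gt$o * tanh(cc)
    Hs[rows, ] <- h
    if (cache) caches[[t]] <- list(gates = gt, c_prev = c_prev, c_t = cc,
                                   h_prev = h_prev)
  }
  list(H = Hs, cache = caches)
}

# LSTM backward; dH (B*T, H) upstream gradient on every hidden output.
lstm_backward <- function(dH, cache, Xmat, B, Tn, Wx, Wh, need_dx = TRUE) {
  nh <- nrow(Wh)
  dWx <- matrix(0, nrow(Wx), ncol(Wx))
  dWh <- matrix(0, nh, 4L * nh)
  db <- numeric(4L * nh)
  dGx <- matrix(0, B * Tn, 4L * nh)
  dh_rec <- matrix(0, B, nh)
  dc <- matrix(0, B, nh)
  for (t in rev(seq_len(Tn))) {
    rows <- (t - 1L) * B + seq_len(B)
    ca <- cache[[t]]
    dh <- dH[rows, , drop = FALSE] + dh_rec
    gb <- gate_backward(dh, dc, ca$gates, ca$c_prev, ca$c_t)
    dc <- gb$dc_prev
    dGx[rows, ] <- gb$dG
    dWh <- dWh + crossprod(ca$h_prev, gb$dG)
    db <- db + colSums(gb$dG)
    dh_rec <- gb$dG %*% t(Wh)
  }
  dWx <- crossprod(Xmat, dGx)
  dX <- if (need_dx) dGx %*% t(Wx) else NULL
  list(dWx = dWx, dWh = dWh, db = db, dX = dX)
}
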