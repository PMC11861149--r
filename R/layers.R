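# Internal network plumbing: the CNN front end (1-D convolution + ReLU +
# max pooling), the dense output head, seeded parameter initialization, and
# Adam. Sequence tensors are arrays with dim (batch, channels, time),
# matching the C++ recurrent kernels.

# Build the im2col matrix for a kernel-3 same-padded 1-D convolution:
# (B*T) x (3*C), offset-major blocks [t-1 | t | t+1].
conv_im2col <- function(Xarr, kernel_size = 3) {
  d <- dim(Xarr); B <- d[1]; C <- d[2]; T <- d[3]
  half <- (kernel_size - 1) %/% 2
  Xpad <- array(0, c(B, C, T + 2 * half))
  Xpad[, , half + seq_len(T)] <- Xarr
  blocks <- lapply(seq_len(kernel_size), function(k) {
    sel <- Xpad[, , (k - 1) + seq_len(T), drop = FALSE]
    m <- aperm(sel, c(1, 3, 2))          # (B, T, C)
    dim(m) <- c(B * T, C)                # row index = b + (t-1)*B
    m
  })
  do.call(cbind, blocks)
}

conv_forward <- function(Xarr, W, b, activation = "relu", pool_size = 2,
                         want_cache = TRUE) {
  d <- dim(Xarr); B <- d[1]; T <- d[3]
  F <- ncol(W)
  Xcol <- conv_im2col(Xarr, kernel_size = nrow(W) / d[2])
  Y <- Xcol %*% W
  Y <- sweep(Y, 2, b, "+")
  relu_mask <- NULL
  if (activation == "relu") {
    relu_mask <- Y > 0
    Y[!relu_mask] <- 0
  }
  if (pool_size <= 1) {
    Yt <- Y; dim(Yt) <- c(B, T, F)
    out <- aperm(Yt, c(1, 3, 2))         # (B, F, T)
    return(list(out = out, cache = if (want_cache)
      list(Xcol = Xcol, relu_mask = relu_mask, argmax = NULL, T = T)))
  }
  stopifnot(pool_size == 2)
  Tp <- T %/% 2
  Yt <- Y; dim(Yt) <- c(B, T, F)
  A <- Yt[, seq(1, 2 * Tp, by = 2), , drop = FALSE]
  Bm <- Yt[, seq(2, 2 * Tp, by = 2), , drop = FALSE]
  take_first <- A >= Bm
  P <- pmax(A, Bm)
  out <- aperm(P, c(1, 3, 2))            # (B, F, Tp)
  list(out = out, cache = if (want_cache)
    list(Xcol = Xcol, relu_mask = relu_mask, take_first = take_first, T = T))
}

conv_backward <- function(dOut, cache, W) {
  # dOut: (B, F, Tp); returns parameter gradients only (the conv is the
  # first layer, gradients w.r.t. the raw input are not needed).
  B <- dim(dOut)[1]; F <- dim(dOut)[2]
  T <- cache$T
  if (!is.null(cache$take_first)) {
    Tp <- dim(dOut)[3]
    dP <- aperm(dOut, c(1, 3, 2))        # (B, Tp, F)
    dY <- array(0, c(B, T, F))
    dA <- dP * cache$take_first
    dB <- dP * !cache$take_first
    dY[, seq(1, 2 * Tp, by = 2), ] <- dA
    dY[, seq(2, 2 * Tp, by = 2), ] <- dB
  } else {
    dY <- aperm(dOut, c(1, 3, 2))
  }
  dim(dY) <- c(B * T, F)
  if (!is.null(cache$relu_mask)) dY <- dY * cache$relu_mask
  list(dW = crossprod(cache$Xcol, dY), db = colSums(dY))
}

#' Apply a 1-D CNN block (convolution, activation, max pooling)
#'
#' Same-padded 1-D convolution along the time axis (kernel size set by the
#' weight matrix), elementwise activation, then non-overlapping max pooling
#' of size `pool_size` (the default 2 halves the sequence: 101 points
#' become 50). This is the front end of every model in the package; it is
#' exported so the block can be exercised and checked on its own.
#'
#' @param x input sequence: a `time x channels` matrix for one sample, or a
#'   `(batch, channels, time)` array.
#' @param W weight matrix `(kernel_size * channels) x n_filters`,
#'   offset-major rows (all channels at offset -1, then 0, then +1).
#' @param b bias vector, length `n_filters`.
#' @param activation `"relu"` or `"linear"`.
#' @param pool_size max-pooling width; `1` disables pooling.
#' @return pooled feature sequence in the same form as the input (matrix
#'   `floor(time/pool) x n_filters`, or array `(batch, n_filters, time')`).
#' @export
cnn_block_forward <- function(x, W, b, activation = c("relu", "linear"),
                              pool_size = 2) {
  activation <- match.arg(activation)
  single <- is.matrix(x)
  if (single) {
    Xarr <- array(t(x), c(1, ncol(x), nrow(x)))
  } else {
    stopifnot(length(dim(x)) == 3)
    Xarr <- x
  }
  if (nrow(W) %% dim(Xarr)[2] != 0) {
    stop("weight rows (", nrow(W), ") are not a multiple of the input channel count (",
         dim(Xarr)[2], ")", call. = FALSE)
  }
  k <- nrow(W) / dim(Xarr)[2]
  if (dim(Xarr)[3] < k) stop("input shorter than the kernel", call. = FALSE)
  out <- conv_forward(Xarr, W, b, activation = activation,
                      pool_size = pool_size, want_cache = FALSE)$out
  if (!single) return(out)
  m <- matrix(out[1, , ], nrow = dim(out)[2], ncol = dim(out)[3])
  t(m)                                   # time x filters
}

dense_forward <- function(Hmat, W, b) sweep(Hmat %*% W, 2, b, "+")

dense_backward <- function(dY, Hmat, W) {
  list(dW = crossprod(Hmat, dY), db = colSums(dY), dH = tcrossprod(dY, W))
}

# ---------------------------------------------------------------- init ----

runif_mat <- function(nr, nc, a) matrix(stats::runif(nr * nc, -a, a), nr, nc)

init_rec_layer <- function(type, input_size, hidden_size) {
  H <- hidden_size
  if (type %in% c("lstm", "slstm")) {
    a <- 1 / sqrt(H)
    b <- numeric(4 * H)
    if (type == "lstm") b[H + 1:H] <- 1  # forget-gate bias, standard
    list(type = type,
         W = runif_mat(input_size, 4 * H, a),
         U = runif_mat(H, 4 * H, a),
         b = b)
  } else if (type == "mlstm") {
    fan <- H + input_size
    list(type = "mlstm",
         Wg = runif_mat(fan, 2 * H, 1 / sqrt(fan)),
         bg = numeric(2 * H),
         Wc = runif_mat(fan, H * H, 1 / sqrt(fan)),
         bc = numeric(H * H),
         Wq = runif_mat(input_size, H, 1 / sqrt(input_size)),
         bq = numeric(H))
  } else stop("unknown recurrent layer type: ", type, call. = FALSE)
}

rec_layer_forward <- function(layer, Xarr, want_cache = TRUE) {
  if (layer$type == "lstm") {
    fw <- cpp_lstm_forward(Xarr, layer$W, layer$U, layer$b)
  } else if (layer$type == "slstm") {
    fw <- cpp_slstm_forward(Xarr, layer$W, layer$U, layer$b)
  } else {
    fw <- cpp_mlstm_forward(Xarr, layer$Wg, layer$bg, layer$Wc, layer$bc,
                            layer$Wq, layer$bq, want_cache)
  }
  fw
}

rec_layer_backward <- function(layer, Xarr, fw, dH) {
  if (layer$type == "lstm") {
    bw <- cpp_lstm_backward(Xarr, layer$W, layer$U, fw$h, fw$c, fw$g, dH)
    list(dX = bw$dX, grads = list(W = bw$dW, U = bw$dU, b = drop(bw$db)))
  } else if (layer$type == "slstm") {
    bw <- cpp_slstm_backward(Xarr, layer$W, layer$U, fw$h, fw$c, fw$n, fw$g, dH)
    list(dX = bw$dX, grads = list(W = bw$dW, U = bw$dU, b = drop(bw$db)))
  } else {
    bw <- cpp_mlstm_backward(Xarr, layer$Wg, layer$Wc, layer$Wq, fw$h, fw$g,
                             fw$q, fw$n, fw$C, fw$M, fw$s, dH)
    list(dX = bw$dX,
         grads = list(Wg = bw$dWg, bg = drop(bw$dbg), Wc = bw$dWc,
                      bc = drop(bw$dbc), Wq = bw$dWq, bq = drop(bw$dbq)))
  }
}

# ---------------------------------------------------------------- Adam ----

adam_init <- function(params) {
  walk <- function(p) {
    if (is.list(p) && is.null(dim(p))) lapply(p, walk)
    else if (is.numeric(p)) array(0, dim = if (is.null(dim(p))) length(p) else dim(p))
    else p
  }
  list(m = walk(params), v = walk(params), t = 0)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(upd, p, g, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else if (is.character(p)) {
      list(p = p, m = m, v = v)
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
    }
  }
  out <- Map(upd, params, grads, state$m, state$v)
  list(params = lapply(out, `[[`, "p"),
       state = list(m = lapply(out, `[[`, "m"),
                    v = lapply(out, `[[`, "v"), t = t))
}
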