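# Shared fixtures and independent oracle implementations. The oracles are
# deliberately naive transcriptions (scalar loops, no stabilization, no
# vectorization tricks) so they stay independent of the package kernels.

make_trials <- function(n = 8, noiseless = TRUE, seed = 99, ...) {
  base <- if (noiseless) list(noise_sd_angle = 0, noise_sd_force = 0) else list()
  generate_gait_dataset(n, base_params = base, seed = seed, ...)
}

# A design with a deterministic linear input-target link (y = first block
# of X), so a column-subset oracle predicts perfectly.
linked_design <- function(n = 30, n_points = 7, seed = 2) {
  set.seed(seed)
  X <- matrix(runif(n * 2 * n_points, 1, 3), n)
  list(name = "toy", X = X, y = X[, seq_len(n_points)],
       speed_kmh = rep(GAIT_SPEEDS, length.out = n))
}

oracle_fit <- function(x_train, y_train, seed) {
  np <- ncol(y_train)
  function(newx) newx[, seq_len(np), drop = FALSE]
}

mean_fit <- function(x_train, y_train, seed) {
  mu <- colMeans(y_train)
  function(newx) matrix(mu, nrow(newx), length(mu), byrow = TRUE)
}

rand_rec_params <- function(type, cin, h, scale = 0.3) {
  if (type %in% c("lstm", "slstm")) {
    list(W = matrix(rnorm(cin * 4 * h, 0, scale), cin, 4 * h),
         U = matrix(rnorm(h * 4 * h, 0, scale), h, 4 * h),
         b = rnorm(4 * h, 0, 0.1))
  } else {
    fan <- h + cin
    list(Wg = matrix(rnorm(fan * 2 * h, 0, scale), fan, 2 * h),
         bg = rnorm(2 * h, 0, 0.1),
         Wc = matrix(rnorm(fan * h * h, 0, scale), fan, h * h),
         bc = rnorm(h * h, 0, 0.1),
         Wq = matrix(rnorm(cin * h, 0, scale), cin, h),
         bq = rnorm(h, 0, 0.1))
  }
}

# Naive sLSTM rollout: direct unstabilized transcription of the printed
# recurrences (exponential gates, normalizer state, c/n readout).
naive_slstm <- function(X, params) {
  # X: T x cin matrix, single sample
  h4 <- ncol(params$W)
  H <- h4 / 4
  c <- n <- h <- numeric(H)
  out <- matrix(NA_real_, nrow(X), H)
  for (t in seq_len(nrow(X))) {
    a <- drop(X[t, ] %*% params$W + h %*% params$U) + params$b
    i <- exp(a[1:H])
    f <- exp(a[H + 1:H])
    z <- tanh(a[2 * H + 1:H])
    o <- 1 / (1 + exp(-a[3 * H + 1:H]))
    c <- f * c + i * z
    n <- f * n + i
    h <- o * (c / n)
    out[t, ] <- h
  }
  out
}

# Naive mLSTM rollout with explicit scalar loops over the memory matrix.
naive_mlstm <- function(X, params) {
  H <- ncol(params$Wq)
  C <- matrix(0, H, H)
  n <- numeric(H)
  h <- numeric(H)
  out <- matrix(NA_real_, nrow(X), H)
  for (t in seq_len(nrow(X))) {
    x <- X[t, ]
    u <- c(h, x)
    g <- 1 / (1 + exp(-(drop(u %*% params$Wg) + params$bg)))
    i <- g[1:H]; f <- g[H + 1:H]
    Mv <- tanh(drop(u %*% params$Wc) + params$bc)
    for (r in seq_len(H)) {
      for (cc in seq_len(H)) {
        C[r, cc] <- f[r] * C[r, cc] + i[r] * Mv[(cc - 1) * H + r]
      }
    }
    q <- drop(x %*% params$Wq) + params$bq
    for (r in seq_len(H)) n[r] <- f[r] * n[r] + i[r]
    den <- max(sum(n * q), 1)
    for (r in seq_len(H)) h[r] <- sum(C[r, ] * q) / den
    out[t, ] <- h
  }
  out
}

# Run the package's batched C++ layer on a single sample given as T x cin.
layer_rollout <- function(type, X, params) {
  Xc <- array(t(X), c(1, ncol(X), nrow(X)))
  layer <- c(list(type = type), params)
  fw <- grfnet:::rec_layer_forward(layer, Xc, want_cache = TRUE)
  t(matrix(fw$h[1, , ], dim(fw$h)[2], dim(fw$h)[3]))
}

# Finite-difference check of a C++ layer's parameter and input gradients
# through a T-step rollout with loss L = sum(dH * h). Returns the worst
# relative error over the probed coordinates.
fd_layer_check <- function(type, B = 2, cin = 2, H = 3, T = 5,
                           n_probe = 10, eps = 1e-5, seed = 1) {
  set.seed(seed)
  X <- array(rnorm(B * cin * T), c(B, cin, T))
  params <- rand_rec_params(type, cin, H)
  dH <- array(rnorm(B * H * T), c(B, H, T))
  pieces <- function(pr, Xa) {
    layer <- c(list(type = type), pr)
    fw <- grfnet:::rec_layer_forward(layer, Xa, want_cache = TRUE)
    bw <- grfnet:::rec_layer_backward(layer, Xa, fw, dH)
    list(loss = sum(fw$h * dH), grads = c(bw$grads, list(X = bw$dX)))
  }
  base <- pieces(params, X)
  worst <- 0
  gscale <- max(abs(unlist(base$grads)))
  for (nm in names(base$grads)) {
    target <- if (nm == "X") X else params[[nm]]
    G <- base$grads[[nm]]
    probe <- unique(round(seq(1, length(target), length.out = n_probe)))
    for (j in probe) {
      old <- target[j]
      target[j] <- old + eps
      lp <- if (nm == "X") pieces(params, target)$loss else {
        p2 <- params; p2[[nm]] <- target; pieces(p2, X)$loss
      }
      target[j] <- old - eps
      lm <- if (nm == "X") pieces(params, target)$loss else {
        p2 <- params; p2[[nm]] <- target; pieces(p2, X)$loss
      }
      target[j] <- old
      fd <- (lp - lm) / (2 * eps)
      rel <- abs(fd - G[j]) / max(abs(fd), abs(G[j]), 1e-4 * gscale)
      worst <- max(worst, rel)
    }
  }
  worst
}
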