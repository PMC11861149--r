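# Recurrent cells: reference R steps vs naive transcription oracles, gate
# algebra, and sequential consistency with the batched C++ layers.

test_that("the LSTM cell-state recurrence obeys its gate algebra", {
  H <- 5
  set.seed(1)
  st <- list(c = rnorm(H), h = rnorm(H))
  z <- tanh(rnorm(H))
  keep <- lstm_step(st, list(i = rep(0, H), f = rep(1, H), o = rep(0.5, H),
                             z = z))
  expect_equal(keep$c, st$c)
  overwrite <- lstm_step(st, list(i = rep(1, H), f = rep(0, H),
                                  o = rep(0.5, H), z = z))
  expect_equal(overwrite$c, z)

  # independent transcription of the update for random gates
  g <- list(i = runif(H), f = runif(H), o = runif(H), z = tanh(rnorm(H)))
  out <- lstm_step(st, g)
  expect_equal(out$c, g$f * st$c + g$i * g$z)
  expect_equal(out$h, g$o * tanh(g$f * st$c + g$i * g$z))

  expect_error(lstm_step(list(c = c(1, NA), h = c(0, 0)),
                         list(i = c(.5, .5), f = c(.5, .5), o = c(.5, .5),
                              z = c(0, 0))), "non-finite")
})

test_that("sLSTM with zero pre-activations counts steps in the normalizer", {
  H <- 3; cin <- 2
  params <- list(W = matrix(0, cin, 4 * H), U = matrix(0, H, 4 * H),
                 b = rep(0, 4 * H))
  st <- slstm_init_state(H)
  for (t in 1:4) {
    st <- slstm_step(st, rnorm(cin), params)
    g <- attr(st, "gates")
    expect_equal(g$i, rep(1, H))     # exp(0) = 1
    expect_equal(g$f, rep(1, H))
    expect_equal(st$n, rep(t, H))    # n_t = n_{t-1} + 1
  }
})

test_that("sLSTM with constant candidate telescopes to the running mean", {
  H <- 4; cin <- 3
  zval <- 0.37
  b <- rep(0, 4 * H)
  b[2 * H + 1:H] <- atanh(zval)      # constant z, i~ = f~ = o~ = 0
  params <- list(W = matrix(0, cin, 4 * H), U = matrix(0, H, 4 * H), b = b)
  st <- slstm_init_state(H)
  for (t in 1:6) {
    st <- slstm_step(st, rnorm(cin), params)
    expect_equal(st$c / st$n, rep(zval, H), tolerance = 1e-12)
    expect_equal(st$h, rep(0.5 * zval, H), tolerance = 1e-12)  # o = sigmoid(0)
  }
})

test_that("sLSTM gates stay positive and finite even for extreme inputs", {
  set.seed(4)
  H <- 4; cin <- 3
  params <- rand_rec_params("slstm", cin, H, scale = 5)
  st <- slstm_init_state(H)
  for (t in 1:30) {
    st <- slstm_step(st, rnorm(cin, sd = 10), params)
    g <- attr(st, "gates")
    expect_true(all(g$i > 0) && all(g$f > 0))
    expect_true(all(is.finite(st$c)) && all(is.finite(st$n)) &&
                  all(is.finite(st$h)))
  }
})

test_that("sLSTM output is invariant to a uniform input-gate bias shift", {
  # adding a constant to every i~ pre-activation scales c and n jointly,
  # so the normalized readout cannot change
  set.seed(9)
  H <- 3; cin <- 2
  params <- rand_rec_params("slstm", cin, H)
  shifted <- params
  shifted$b[1:H] <- shifted$b[1:H] + 2.5
  X <- matrix(rnorm(6 * cin), 6, cin)
  st1 <- slstm_init_state(H); st2 <- slstm_init_state(H)
  for (t in 1:6) {
    st1 <- slstm_step(st1, X[t, ], params)
    st2 <- slstm_step(st2, X[t, ], shifted)
  }
  expect_equal(st1$h, st2$h, tolerance = 1e-10)
})

test_that("stabilized sLSTM matches the naive transcription where it is finite", {
  set.seed(11)
  for (rep in 1:10) {
    cin <- sample(2:3, 1); H <- sample(2:4, 1); T <- 12
    params <- rand_rec_params("slstm", cin, H)
    X <- matrix(rnorm(T * cin, sd = 0.5), T, cin)
    ref <- naive_slstm(X, params)
    st <- slstm_init_state(H)
    for (t in seq_len(T)) st <- slstm_step(st, X[t, ], params)
    expect_equal(st$h, ref[T, ], tolerance = 1e-6)
  }
})

test_that("mLSTM memory freezes under saturated forget / closed input gates", {
  set.seed(13)
  H <- 3; cin <- 2
  params <- rand_rec_params("mlstm", cin, H)
  params$bg <- c(rep(-40, H), rep(40, H))    # i -> 0, f -> 1
  st <- mlstm_init_state(H)
  st$C <- matrix(rnorm(H * H), H, H); st$n <- runif(H)
  out <- mlstm_step(st, rnorm(cin), rnorm(H), params)
  expect_equal(out$C, st$C, tolerance = 1e-12)
  expect_equal(out$n, st$n, tolerance = 1e-12)
})

test_that("the mLSTM readout denominator clamps at 1", {
  set.seed(14)
  H <- 3; cin <- 2
  params <- rand_rec_params("mlstm", cin, H, scale = 0.05)
  st <- mlstm_init_state(H)
  x <- rnorm(cin, sd = 0.05)
  out <- mlstm_step(st, x, numeric(H), params)
  q <- drop(x %*% params$Wq) + params$bq
  s <- sum(out$n * q)
  expect_lt(abs(s), 1)                       # small regime: clamp active
  expect_equal(out$h, drop(out$C %*% q))     # denominator exactly 1

  # large regime: denominator is n'q itself
  params2 <- rand_rec_params("mlstm", cin, H, scale = 1)
  params2$bq <- rep(30, H); params2$bg <- rep(5, 2 * H)
  out2 <- mlstm_step(mlstm_init_state(H), x, numeric(H), params2)
  q2 <- drop(x %*% params2$Wq) + params2$bq
  s2 <- sum(out2$n * q2)
  expect_gt(s2, 1)
  expect_equal(out2$h, drop(out2$C %*% q2) / s2)
})

test_that("mLSTM rejects a query/memory shape mismatch", {
  H <- 3; cin <- 2
  params <- rand_rec_params("mlstm", cin, H)
  params$Wq <- matrix(0, cin, H + 1); params$bq <- numeric(H + 1)
  expect_error(mlstm_step(mlstm_init_state(H), rnorm(cin), numeric(H), params),
               "does not match memory columns")
})

test_that("mLSTM steps match the scalar-loop transcription oracle", {
  set.seed(15)
  for (rep in 1:10) {
    cin <- sample(2:3, 1); H <- sample(2:4, 1); T <- 10
    params <- rand_rec_params("mlstm", cin, H)
    X <- matrix(rnorm(T * cin, sd = 0.5), T, cin)
    ref <- naive_mlstm(X, params)
    st <- mlstm_init_state(H); h <- numeric(H)
    for (t in seq_len(T)) {
      out <- mlstm_step(st, X[t, ], h, params)
      st$C <- out$C; st$n <- out$n; h <- out$h
    }
    expect_equal(h, ref[T, ], tolerance = 1e-8)
  }
})

test_that("batched C++ layers reproduce the R reference steps sample by sample", {
  set.seed(16)
  B <- 4; cin <- 3; H <- 5; T <- 7
  X <- array(rnorm(B * cin * T), c(B, cin, T))

  sp <- rand_rec_params("slstm", cin, H)
  fw <- grfnet:::cpp_slstm_forward(X, sp$W, sp$U, sp$b)
  for (b in 1:B) {
    st <- slstm_init_state(H)
    for (t in 1:T) st <- slstm_step(st, X[b, , t], sp)
    expect_equal(fw$h[b, , T], st$h, tolerance = 1e-12)
    expect_equal(fw$n[b, , T], st$n, tolerance = 1e-12)
  }

  mp <- rand_rec_params("mlstm", cin, H)
  fwm <- grfnet:::cpp_mlstm_forward(X, mp$Wg, mp$bg, mp$Wc, mp$bc, mp$Wq,
                                    mp$bq, TRUE)
  for (b in 1:B) {
    st <- mlstm_init_state(H); h <- numeric(H)
    for (t in 1:T) {
      out <- mlstm_step(st, X[b, , t], h, mp)
      st$C <- out$C; st$n <- out$n; h <- out$h
    }
    expect_equal(fwm$h[b, , T], h, tolerance = 1e-12)
  }

  lp <- rand_rec_params("lstm", cin, H)
  fwl <- grfnet:::cpp_lstm_forward(X, lp$W, lp$U, lp$b)
  for (b in 1:B) {
    st <- list(c = numeric(H), h = numeric(H))
    for (t in 1:T) {
      a <- drop(X[b, , t] %*% lp$W + st$h %*% lp$U) + lp$b
      st <- lstm_step(st, list(i = 1 / (1 + exp(-a[1:H])),
                               f = 1 / (1 + exp(-a[H + 1:H])),
                               z = tanh(a[2 * H + 1:H]),
                               o = 1 / (1 + exp(-a[3 * H + 1:H]))))
    }
    expect_equal(fwl$h[b, , T], st$h, tolerance = 1e-12)
  }
})

test_that("the CNN block matches a naive convolution oracle and the identity case", {
  set.seed(17)
  T <- 12; C <- 2; F <- 3
  x <- matrix(rnorm(T * C), T, C)
  W <- matrix(rnorm(3 * C * F), 3 * C, F)
  b <- rnorm(F)
  out <- cnn_block_forward(x, W, b, activation = "linear", pool_size = 1)
  # naive O(T*k) loop oracle, zero padding
  xp <- rbind(0, x, 0)
  ref <- matrix(0, T, F)
  for (t in 1:T) for (f in 1:F) {
    acc <- b[f]
    for (k in 1:3) for (ch in 1:C) {
      acc <- acc + xp[t + k - 1, ch] * W[(k - 1) * C + ch, f]
    }
    ref[t, f] <- acc
  }
  expect_equal(out, ref, tolerance = 1e-12)

  # identity kernel [0, 1, 0], single filter, no pooling
  Wi <- matrix(c(0, 1, 0), 3, 1)
  xi <- matrix(rnorm(T), T, 1)
  expect_equal(cnn_block_forward(xi, Wi, 0, "linear", pool_size = 1), xi,
               ignore_attr = TRUE)

  # pooling halves the sequence: 101 -> 50, and pairs take their max
  x101 <- matrix(rnorm(101), 101, 1)
  pooled <- cnn_block_forward(x101, Wi, 0, "linear", pool_size = 2)
  expect_equal(nrow(pooled), 50)
  expect_equal(drop(pooled), pmax(x101[seq(1, 99, 2), 1], x101[seq(2, 100, 2), 1]))
})
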