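# Preprocessing chain: stance detection, filtering, time normalization,
# min-max scaling, and the seven design-matrix factorizations.

test_that("stance detection follows the 10 N half-open window definition", {
  expect_error(detect_stance(rep(0, 100)), "no stance found")

  w <- detect_stance(c(0, 5, 11, 50, 11, 5, 0), sample_rate_hz = 1000)
  expect_equal(w$start, 2)   # first sample strictly above 10 N (0-based)
  expect_equal(w$end, 5)     # first subsequent sample at or below 10 N
  expect_false(w$truncated)
  expect_identical(stance_slice(c(0, 5, 11, 50, 11, 5, 0), w),
                   c(11, 50, 11))
})

test_that("stance windows equal a brute-force threshold scan on synthetic trials", {
  ds <- make_trials(6, noiseless = FALSE, seed = 31)
  for (tr in ds$trials) {
    f <- butterworth_lowpass(as.numeric(tr$force), filter_spec(10, 1000))
    w <- detect_stance(f)
    # exhaustive scan oracle (no debounce needed on filtered data)
    above <- which(f > 10)
    start <- above[1] - 1
    after <- which(f <= 10 & seq_along(f) > above[1])
    end <- after[1] - 1
    expect_equal(w$start, start)
    expect_equal(w$end, end)
  }
})

test_that("short sub-threshold dips are bridged, real lift-off is not", {
  f <- c(0, 0, 20, 30, 8, 9, 30, 20, 0, 0)          # 2-sample dip (chatter)
  w <- detect_stance(f, sample_rate_hz = 1000, debounce_s = 0.005)
  expect_equal(c(w$start, w$end), c(2, 8))
  w2 <- detect_stance(f, sample_rate_hz = 1000, debounce_s = 0.001)
  expect_equal(c(w2$start, w2$end), c(2, 4))        # 1-sample debounce: split
})

test_that("a force that never returns below threshold warns and truncates", {
  expect_warning(w <- detect_stance(c(0, 0, 20, 30, 40, 50)), "series end")
  expect_true(w$truncated)
  expect_equal(c(w$start, w$end), c(2, 6))
})

test_that("the Butterworth filter passes DC and rejects far-above-cutoff tones", {
  spec <- filter_spec(10, 1000)
  const <- rep(3.7, 500)
  expect_equal(butterworth_lowpass(const, spec), const, tolerance = 1e-8)

  t <- seq(0, 1, by = 1e-3)
  tone <- sin(2 * pi * 50 * t)                      # 5x the 10 Hz cutoff
  out <- butterworth_lowpass(tone, spec)
  # FFT amplitude oracle at the tone frequency
  amp_at <- function(x, f_hz) {
    sp <- stats::fft(x)
    idx <- round(f_hz * length(x) / 1000) + 1
    Mod(sp[idx])
  }
  expect_lt(amp_at(out, 50) / amp_at(tone, 50), 0.05)
  expect_lt(sqrt(mean(out^2)) / sqrt(mean(tone^2)), 0.05)

  expect_error(filter_spec(600, 1000), "Nyquist")
  expect_error(filter_spec(10, 1000, order = 3))
})

test_that("time normalization hits 101 points with exact endpoints", {
  ramp <- seq(2, 8, length.out = 37)
  out <- time_normalize(ramp)
  expect_length(out, 101)
  expect_equal(out, seq(2, 8, length.out = 101))    # closed-form line

  x <- sin(seq(0, 3, length.out = 101))
  expect_equal(time_normalize(x), x)                # identity on the grid

  y <- cumsum(rnorm(237))
  out2 <- time_normalize(y)
  expect_length(out2, 101)
  expect_identical(out2[1], y[1])
  expect_identical(out2[101], y[237])

  expect_error(time_normalize(3), "at least 2")
})

test_that("time normalization is idempotent for the linear interpolant", {
  set.seed(8)
  s <- cumsum(rnorm(83))
  once <- time_normalize(s)
  expect_equal(time_normalize(once), once, tolerance = 1e-12)
})

test_that("min-max scaling follows the worked example and round-trips", {
  r <- minmax_fit_transform(matrix(c(2, 4, 6), ncol = 1))
  expect_equal(drop(r$x), c(0, 0.5, 1))

  set.seed(2)
  X <- matrix(rnorm(60), 12, 5)
  ft <- minmax_fit_transform(X)
  expect_equal(apply(ft$x, 2, min), rep(0, 5), ignore_attr = TRUE)
  expect_equal(apply(ft$x, 2, max), rep(1, 5), ignore_attr = TRUE)
  back <- minmax_inverse(ft$x, ft$params)
  expect_equal(back, X, tolerance = 1e-12, ignore_attr = TRUE)

  # test-fold reuse: parameters frozen, output may leave [0, 1]
  Xte <- X + 2
  te <- minmax_fit_transform(Xte, ft$params)
  expect_identical(te$params, ft$params)
  expect_gt(max(te$x), 1)

  expect_warning(cz <- minmax_fit_transform(cbind(X[, 1], 7)), "constant")
  expect_true(all(cz$x[, 2] == 0))
})

test_that("the seven designs have the documented shapes and channel subsets", {
  ds <- make_trials(6, seed = 17)
  designs <- assemble_designs(ds$trials)
  expect_named(designs, paste0("M", 1:7))
  expect_equal(ncol(designs$M1$X), 909)
  expect_equal(nrow(designs$M1$X), 6)
  for (nm in paste0("M", 2:7)) expect_equal(ncol(designs[[nm]]$X), 303)

  # M5 = sagittal subset of M1, element for element (index-selection oracle)
  sag_cols <- as.vector(vapply(c(1L, 4L, 7L),
                               function(ch) (ch - 1L) * 101L + 1:101,
                               integer(101)))
  expect_identical(designs$M5$X, designs$M1$X[, sag_cols])
  expect_identical(designs$M2$X, designs$M1$X[, 1:303])   # ankle block
  expect_identical(designs$M1$y, designs$M5$y)

  # channel order is joint-major with sagittal/frontal/transversal planes
  expect_equal(designs$M1$channel_layout$joint,
               rep(c("ankle", "hip", "knee"), each = 3))
  expect_equal(designs$M6$channel_layout$plane, rep("frontal", 3))
})

test_that("targets are body-weight scaled and near the configured peaks", {
  ds <- make_trials(4, seed = 19)
  designs <- assemble_designs(ds$trials)
  y <- designs$M1$y
  expect_true(all(y >= -0.05) && all(y < 3.5))      # plausible BW range
  expect_true(all(abs(apply(y, 1, max) -
                        vapply(ds$trials, function(tr) tr$params$active_peak_bw, 0)) < 0.35))
})

test_that("trials without a detectable stance are dropped with a message", {
  ds <- make_trials(3, seed = 23)
  dead <- gait_params(12, impact_peak_bw = 0, active_peak_bw = 0,
                      coupling_gain_bw = 0, noise_sd_force = 0,
                      noise_sd_angle = 0)
  flat <- ds$trials[[1]]
  flat$trial_id <- "flat01"
  flat$angles <- generate_joint_angles(dead)
  flat$force <- generate_vgrf(dead, flat$angles)
  msgs <- capture_messages(designs <- assemble_designs(c(ds$trials, list(flat))))
  expect_match(paste(msgs, collapse = "\n"), "flat01")
  expect_match(paste(msgs, collapse = "\n"), "dropped")
  expect_equal(nrow(designs$M1$X), 3)
  expect_false("flat01" %in% designs$M1$trial_id)
})
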