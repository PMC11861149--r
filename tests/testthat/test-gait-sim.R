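# Synthetic gait generator: determinism, closed-form basis agreement,
# double-peak vGRF shape, dataset assembly and learnability.

test_that("angle generation is deterministic and has the right grid", {
  p <- gait_params(speed_kmh = 12, stance_duration_s = 0.25)
  set.seed(5); a1 <- generate_joint_angles(p)
  set.seed(5); a2 <- generate_joint_angles(p)
  expect_identical(a1, a2)
  expect_equal(nrow(a1), 50)   # 0.25 s x 200 Hz
  expect_equal(ncol(a1), 9)

  p0 <- gait_params(speed_kmh = 12, noise_sd_angle = 0)
  b1 <- generate_joint_angles(p0)
  b2 <- generate_joint_angles(p0)
  expect_identical(b1, b2)     # noiseless output needs no seed at all
})

test_that("noiseless angles equal a direct evaluation of the cosine basis", {
  for (sp in c(8, 16)) {
    p <- gait_params(speed_kmh = sp, noise_sd_angle = 0)
    ang <- generate_joint_angles(p)
    u <- seq(0, 1, length.out = nrow(ang))
    # independent transcription of the documented basis
    cf <- p$angle_basis_coeffs
    for (ch in seq_len(9)) {
      expected <- rep(cf[ch, 1], length(u))
      for (k in 1:4) expected <- expected + cf[ch, k + 1] * cos(k * pi * u)
      expect_equal(unname(ang[, ch]), expected, tolerance = 1e-12)
    }
  }
})

test_that("speed scales the sagittal curves as documented", {
  p8 <- gait_params(8, noise_sd_angle = 0)
  p16 <- gait_params(16, noise_sd_angle = 0)
  a8 <- generate_joint_angles(p8); a16 <- generate_joint_angles(p16)
  # amplitudes differ by the documented linear coefficient scaling
  amp <- function(a) diff(range(a))
  expect_gt(amp(a16[, "hip_sagittal"]), amp(a8[, "hip_sagittal"]))
  # sagittal channels dominate the out-of-plane ones
  for (j in c("ankle", "hip", "knee")) {
    expect_gt(amp(a16[, paste0(j, "_sagittal")]),
              amp(a16[, paste0(j, "_frontal")]))
    expect_gt(amp(a16[, paste0(j, "_sagittal")]),
              amp(a16[, paste0(j, "_transversal")]))
  }
})

test_that("invalid speeds are rejected with the allowed list", {
  expect_error(gait_params(speed_kmh = 9), "allowed speeds are 8, 10, 12, 14, 16")
  expect_error(generate_gait_dataset(4, speeds = c(8, 11)), "allowed speeds")
  expect_error(generate_gait_dataset(4, speeds = numeric(0)), "empty")
})

test_that("noiseless vGRF is double-peaked with quiet edges", {
  p <- gait_params(12, noise_sd_force = 0, noise_sd_angle = 0)
  ang <- generate_joint_angles(p)
  f <- generate_vgrf(p, ang)
  # 50 Hz smoothing: removes sample-level roughness without flattening the
  # ~20 ms impact transient (the 10 Hz analysis filter would merge it)
  sm <- butterworth_lowpass(as.numeric(f), filter_spec(50, 1000))
  # strict local maxima above a small floor (numerical plateaus excluded)
  dx <- diff(sm)
  peaks <- which(dx[-length(dx)] > 0 & dx[-1] < 0) + 1
  peaks <- peaks[sm[peaks] > 0.2 * max(sm)]
  expect_identical(length(peaks), 2L)
  expect_lt(f[1], 10); expect_lt(f[length(f)], 10)
  n_pad <- round(0.05 * 1000)
  expect_lt(max(f[seq_len(n_pad)]), 10)          # leading pad below threshold
  expect_lt(max(f[length(f) - seq_len(n_pad) + 1]), 10)
})

test_that("zero peaks and zero coupling give identically zero force", {
  p <- gait_params(12, impact_peak_bw = 0, active_peak_bw = 0,
                   coupling_gain_bw = 0, noise_sd_force = 0,
                   noise_sd_angle = 0)
  f <- generate_vgrf(p, generate_joint_angles(p))
  expect_true(all(f == 0))
})

test_that("sampled peak heights match the configured BW peaks within the documented bound", {
  for (sp in c(8, 12, 16)) {
    p <- gait_params(sp, noise_sd_force = 0, noise_sd_angle = 0)
    f <- generate_vgrf(p, generate_joint_angles(p))
    bw <- as.numeric(f) / (p$body_mass_kg * 9.81)
    bound <- vgrf_peak_bound(p)
    # brute-force scan: global max is the active peak; impact peak is the
    # max over the early stance region
    expect_lt(abs(max(bw) - p$active_peak_bw), bound["active"] + 1e-9)
    n_pad <- round(0.05 * 1000)
    n_st <- round(p$stance_duration_s * 1000)
    early <- n_pad + seq_len(round(0.25 * n_st))
    expect_lt(abs(max(bw[early]) - p$impact_peak_bw), bound["impact"] + 1e-9)
  }
})

test_that("angle/param mismatch is rejected", {
  p1 <- gait_params(8); p2 <- gait_params(16)
  ang <- generate_joint_angles(p1)
  expect_error(generate_vgrf(p2, ang), "mismatch")
})

test_that("datasets cycle speeds round-robin and are seed-reproducible", {
  ds <- make_trials(10, seed = 3)
  expect_identical(as.vector(table(ds$manifest$speed_kmh)), rep(2L, 5))
  ds2 <- make_trials(10, seed = 3)
  expect_identical(ds$manifest, ds2$manifest)
  expect_identical(ds$trials[[7]]$force, ds2$trials[[7]]$force)
  ds3 <- make_trials(10, seed = 4)
  expect_false(identical(ds$trials[[1]]$force, ds3$trials[[1]]$force))
})

test_that("written manifests are byte-identical across reruns", {
  d1 <- file.path(tempdir(), "gaitA"); d2 <- file.path(tempdir(), "gaitB")
  generate_gait_dataset(4, seed = 11, dir = d1)
  generate_gait_dataset(4, seed = 11, dir = d2)
  expect_identical(readLines(file.path(d1, "manifest.csv")),
                   readLines(file.path(d2, "manifest.csv")))
  expect_identical(unname(tools::md5sum(file.path(d1, "trial0001_force.csv"))),
                   unname(tools::md5sum(file.path(d2, "trial0001_force.csv"))))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("stance-duration jitter matches the documented uniform bounds", {
  ds <- make_trials(40, seed = 21, speeds = 12)
  dur <- vapply(ds$trials, function(tr) tr$params$stance_duration_s, 0)
  base <- 0.340 - 0.009 * 12
  # Monte-Carlo oracle: the same uniform jitter, resampled directly
  set.seed(1); oracle <- base * runif(20000, 0.92, 1.08)
  expect_true(all(dur >= min(oracle) - 1e-12 & dur <= max(oracle) + 1e-12))
  expect_gt(stats::sd(dur), 0)
  expect_lt(abs(mean(dur) - mean(oracle)), 3 * stats::sd(oracle) / sqrt(40))
})

test_that("a linear ridge fit from angles to vGRF beats the mean (learnability)", {
  ds <- make_trials(20, seed = 13)
  designs <- assemble_designs(ds$trials)
  d <- designs$M1
  tr <- seq(1, 20, by = 2); te <- seq(2, 20, by = 2)
  X <- cbind(1, d$X[tr, ]); Xte <- cbind(1, d$X[te, ])
  lambda <- 1e-3
  beta <- solve(crossprod(X) + lambda * diag(ncol(X)), crossprod(X, d$y[tr, ]))
  expect_gt(r_squared(d$y[te, ], Xte %*% beta), 0)
})
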