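# Synthetic running-gait generator: smooth speed-dependent joint-angle
# curves on a 200 Hz grid and a double-peak vGRF on a 1000 Hz grid, coupled
# so the regression target is learnable from the inputs.

GRAVITY <- 9.81          # m/s^2
ANGLE_RATE_HZ <- 200
FORCE_RATE_HZ <- 1000
FORCE_PAD_S <- 0.05      # zero-force padding on each side of stance
EDGE_TAPER_FRAC <- 0.03  # stance fraction over which the vGRF is tapered to 0

# Nominal sagittal amplitudes (deg) used to scale the coupling term to O(1).
COUPLING_ANKLE_SCALE <- 30
COUPLING_KNEE_SCALE <- 40

#' Evaluate the half-cycle cosine angle basis
#'
#' `theta(u) = a0 + sum_{k=1..4} ak * cos(k * pi * u)` with `u` the stance
#' fraction in `[0, 1]`. This closed form is the noise-free backbone of
#' every generated angle channel.
#'
#' @param coeffs numeric vector `c(a0, ..., a4)` or a 9 x 5 matrix (one row
#'   per channel).
#' @param u stance fractions in `[0, 1]`.
#' @return numeric vector (or `length(u)` x 9 matrix) of angles in degrees.
#' @export
eval_angle_basis <- function(coeffs, u) {
  B <- cbind(1, cos(pi * u), cos(2 * pi * u), cos(3 * pi * u), cos(4 * pi * u))
  if (is.matrix(coeffs)) {
    out <- B %*% t(coeffs)
    colnames(out) <- rownames(coeffs)
    out
  } else {
    drop(B %*% coeffs)
  }
}

#' Generate the 9 joint-angle series for one stance phase
#'
#' Evaluates the smooth basis of `params$angle_basis_coeffs` on a 200 Hz
#' grid spanning `stance_duration_s` and adds i.i.d. Gaussian noise of sd
#' `noise_sd_angle` (degrees). Uses the current R random stream; seed with
#' `set.seed()` (or via [generate_gait_dataset()]) for reproducibility.
#'
#' @param params a [gait_params()] object.
#' @return matrix `n_samples x 9` (columns in [channel_layout()] order) with
#'   attributes `time_s` (seconds, offset by the force-channel padding so
#'   the two files share a clock) and `speed_kmh`.
#' @export
generate_joint_angles <- function(params) {
  stopifnot(inherits(params, "gait_params"))
  n <- round(params$stance_duration_s * ANGLE_RATE_HZ)
  if (n < 2) stop("stance too short for the 200 Hz angle grid", call. = FALSE)
  u <- seq(0, 1, length.out = n)
  ang <- eval_angle_basis(params$angle_basis_coeffs, u)
  if (params$noise_sd_angle > 0) {
    ang <- ang + matrix(stats::rnorm(length(ang), 0, params$noise_sd_angle),
                        nrow = n)
  }
  colnames(ang) <- channel_names()
  attr(ang, "time_s") <- FORCE_PAD_S + u * params$stance_duration_s
  attr(ang, "speed_kmh") <- params$speed_kmh
  ang
}

# Asymmetric Gaussian bump in stance-fraction coordinates: width sigma_l
# left of the mode, sigma_r right of it.
asym_gauss <- function(u, mu, sigma_l, sigma_r) {
  s <- ifelse(u < mu, sigma_l, sigma_r)
  exp(-0.5 * ((u - mu) / s)^2)
}

smoothstep01 <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

# Template bump widths (stance fractions). The active bump's left side is
# kept narrow so its leakage under the impact peak stays small; the leakage
# bound used in tests is vgrf_peak_bound().
IMPACT_SIGMA <- c(l = 0.040, r = 0.050)
ACTIVE_SIGMA <- c(l = 0.120, r = 0.200)

# Noise-free vGRF curve in body weights on stance fractions u.
vgrf_bw_curve <- function(params, u) {
  templ <-
    params$impact_peak_bw *
      asym_gauss(u, params$impact_peak_frac, IMPACT_SIGMA["l"], IMPACT_SIGMA["r"]) +
    params$active_peak_bw *
      asym_gauss(u, params$active_peak_frac, ACTIVE_SIGMA["l"], ACTIVE_SIGMA["r"])
  a_hat <- eval_angle_basis(params$angle_basis_coeffs["ankle_sagittal", ], u) /
    COUPLING_ANKLE_SCALE
  k_hat <- eval_angle_basis(params$angle_basis_coeffs["knee_sagittal", ], u) /
    COUPLING_KNEE_SCALE
  coup <- params$coupling_gain_bw * sin(pi * u)^2 * 0.5 * (a_hat^2 + k_hat^2)
  taper <- smoothstep01(u / EDGE_TAPER_FRAC) *
    smoothstep01((1 - u) / EDGE_TAPER_FRAC)
  (templ + coup) * taper
}

#' Bound on the deviation of vGRF peak samples from the configured peaks
#'
#' The sampled maxima of the noise-free vGRF differ from `impact_peak_bw` /
#' `active_peak_bw` only through (a) the angle-coupling term, bounded by its
#' gain times the maximal quadratic term, and (b) the leakage of the other
#' template bump at the peak location. Returns that bound in body weights,
#' one value per peak.
#'
#' @param params a [gait_params()] object.
#' @return named numeric vector `c(impact = , active = )`.
#' @export
vgrf_peak_bound <- function(params) {
  u <- seq(0, 1, length.out = 2001)
  a_hat <- eval_angle_basis(params$angle_basis_coeffs["ankle_sagittal", ], u) /
    COUPLING_ANKLE_SCALE
  k_hat <- eval_angle_basis(params$angle_basis_coeffs["knee_sagittal", ], u) /
    COUPLING_KNEE_SCALE
  coup_max <- params$coupling_gain_bw * max(0.5 * (a_hat^2 + k_hat^2))
  leak_at_impact <- params$active_peak_bw *
    asym_gauss(params$impact_peak_frac, params$active_peak_frac,
               ACTIVE_SIGMA["l"], ACTIVE_SIGMA["r"])
  leak_at_active <- params$impact_peak_bw *
    asym_gauss(params$active_peak_frac, params$impact_peak_frac,
               IMPACT_SIGMA["l"], IMPACT_SIGMA["r"])
  c(impact = coup_max + leak_at_impact, active = coup_max + leak_at_active)
}

#' Generate the vertical ground reaction force for one trial
#'
#' Builds the stance-phase vGRF as `body_mass * g` times a double-peak
#' template (two asymmetric Gaussian bumps at the configured stance
#' fractions) plus a quadratic coupling to the noise-free sagittal ankle and
#' knee angle curves, tapered to zero at the stance edges, padded with 50 ms
#' of zero force on each side (so the 10 N stance rule has something to
#' detect), with Gaussian noise of sd `noise_sd_force` body weights, and
#' clipped at 0 N.
#'
#' @param params a [gait_params()] object.
#' @param angles the matrix returned by [generate_joint_angles()] for the
#'   same `params` (consistency is checked).
#' @return numeric vector of force (N) at 1000 Hz with attribute `time_s`.
#' @export
generate_vgrf <- function(params, angles) {
  stopifnot(inherits(params, "gait_params"))
  n_exp <- round(params$stance_duration_s * ANGLE_RATE_HZ)
  if (!is.matrix(angles) || ncol(angles) != 9 || nrow(angles) != n_exp ||
      !identical(attr(angles, "speed_kmh"), params$speed_kmh)) {
    stop("angle/param mismatch: angles were not generated from these params",
         call. = FALSE)
  }
  n_st <- round(params$stance_duration_s * FORCE_RATE_HZ)
  n_pad <- round(FORCE_PAD_S * FORCE_RATE_HZ)
  u <- seq(0, 1, length.out = n_st)
  bw <- params$body_mass_kg * GRAVITY
  force <- c(numeric(n_pad), bw * vgrf_bw_curve(params, u), numeric(n_pad))
  if (params$noise_sd_force > 0) {
    force <- force + stats::rnorm(length(force), 0, params$noise_sd_force * bw)
  }
  force <- pmax(force, 0)
  attr(force, "time_s") <- (seq_along(force) - 1) / FORCE_RATE_HZ
  force
}

#' Generate a full synthetic gait dataset
#'
#' Draws `n_trials` stance-phase trials round-robin over the requested
#' speeds and over `n_subjects` synthetic subjects (body masses drawn once
#' from N(72.5, 9.55^2) kg, the anthropometrics of a typical young male
#' runner cohort). Per trial, the peak magnitudes and timings are jittered
#' by `jitter` (uniform, +/-10% by default) and the stance duration by
#' `duration_jitter`, giving variable-length stances. Fully reproducible
#' from `seed`.
#'
#' @param n_trials number of trials (>= 1).
#' @param speeds nominal speeds to cycle over; subset of [GAIT_SPEEDS].
#' @param base_params named list of overrides passed to [gait_params()]
#'   (e.g. `list(noise_sd_force = 0)` for noiseless data).
#' @param seed integer seed controlling all randomness.
#' @param dir optional directory; when given, one angle CSV and one force
#'   CSV per trial plus `manifest.csv` are written (see [write_gait_dataset()]).
#' @param n_subjects number of synthetic subjects.
#' @param jitter relative half-width of the uniform jitter on peak
#'   magnitudes and timings.
#' @param duration_jitter relative half-width of the uniform jitter on
#'   stance duration.
#' @return list with elements `trials` (list of `gait_trial` objects: fields
#'   `trial_id`, `subject_id`, `speed_kmh`, `body_mass_kg`, `angles`,
#'   `force`) and `manifest` (data.frame).
#' @export
generate_gait_dataset <- function(n_trials = 530,
                                  speeds = GAIT_SPEEDS,
                                  base_params = list(),
                                  seed = 1,
                                  dir = NULL,
                                  n_subjects = 12,
                                  jitter = 0.10,
                                  duration_jitter = 0.08) {
  if (length(speeds) == 0) stop("speed list must not be empty", call. = FALSE)
  stopifnot(n_trials >= 1, n_subjects >= 1)
  for (s in speeds) check_speed(s)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  masses <- pmax(stats::rnorm(n_subjects, 72.5, 9.55), 45)

  trials <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    sp <- speeds[((i - 1) %% length(speeds)) + 1]
    subj <- ((i - 1) %% n_subjects) + 1
    args <- c(list(speed_kmh = sp, body_mass_kg = masses[subj]), base_params)
    p <- do.call(gait_params, args)
    jit <- function(x, w) x * stats::runif(1, 1 - w, 1 + w)
    p$impact_peak_bw <- jit(p$impact_peak_bw, jitter)
    p$active_peak_bw <- jit(p$active_peak_bw, jitter)
    p$impact_peak_frac <- jit(p$impact_peak_frac, jitter)
    p$active_peak_frac <- jit(p$active_peak_frac, jitter)
    p$stance_duration_s <- jit(p$stance_duration_s, duration_jitter)
    stopifnot(p$impact_peak_frac < p$active_peak_frac)
    ang <- generate_joint_angles(p)
    frc <- generate_vgrf(p, ang)
    trials[[i]] <- structure(list(
      trial_id = sprintf("trial%04d", i),
      subject_id = sprintf("subj%02d", subj),
      speed_kmh = sp,
      body_mass_kg = p$body_mass_kg,
      params = p,
      angles = ang,
      force = frc
    ), class = "gait_trial")
  }
  manifest <- data.frame(
    trial_id = vapply(trials, `[[`, "", "trial_id"),
    subject_id = vapply(trials, `[[`, "", "subject_id"),
    speed_kmh = vapply(trials, `[[`, 0, "speed_kmh"),
    body_mass_kg = vapply(trials, `[[`, 0, "body_mass_kg"),
    angles_file = paste0(vapply(trials, `[[`, "", "trial_id"), "_angles.csv"),
    force_file = paste0(vapply(trials, `[[`, "", "trial_id"), "_force.csv"),
    stringsAsFactors = FALSE
  )
  ds <- list(trials = trials, manifest = manifest)
  if (!is.null(dir)) write_gait_dataset(ds, dir)
  ds
}

fmt_num <- function(x) sprintf("%.10g", x)

#' Write a gait dataset as per-trial CSV files plus a manifest
#'
#' One 200 Hz angle file per trial (`time_s` + 9 `<joint>_<plane>_deg`
#' columns), one 1000 Hz force file (`time_s`, `force_N`), and
#' `manifest.csv`. Floats carry 10 significant digits; the output is
#' byte-stable for a fixed dataset.
#'
#' @param dataset result of [generate_gait_dataset()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_gait_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tr in dataset$trials) {
    adf <- data.frame(time_s = fmt_num(attr(tr$angles, "time_s")))
    for (j in seq_len(ncol(tr$angles))) {
      adf[[paste0(colnames(tr$angles)[j], "_deg")]] <- fmt_num(tr$angles[, j])
    }
    utils::write.csv(adf, file.path(dir, paste0(tr$trial_id, "_angles.csv")),
                     row.names = FALSE, quote = FALSE)
    fdf <- data.frame(time_s = fmt_num(attr(tr$force, "time_s")),
                      force_N = fmt_num(as.numeric(tr$force)))
    utils::write.csv(fdf, file.path(dir, paste0(tr$trial_id, "_force.csv")),
                     row.names = FALSE, quote = FALSE)
  }
  man <- dataset$manifest
  man$body_mass_kg <- fmt_num(man$body_mass_kg)
  utils::write.csv(man, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a gait dataset written by [write_gait_dataset()]
#'
#' @param dir directory containing `manifest.csv` and the trial files.
#' @return list with `trials` and `manifest`, as [generate_gait_dataset()].
#' @export
read_gait_dataset <- function(dir) {
  man_path <- file.path(dir, "manifest.csv")
  if (!file.exists(man_path)) stop("no manifest.csv in ", dir, call. = FALSE)
  manifest <- utils::read.csv(man_path, stringsAsFactors = FALSE)
  trials <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    adf <- utils::read.csv(file.path(dir, row$angles_file))
    ang <- as.matrix(adf[, -1, drop = FALSE])
    colnames(ang) <- sub("_deg$", "", colnames(ang))
    attr(ang, "time_s") <- adf$time_s
    fdf <- utils::read.csv(file.path(dir, row$force_file))
    frc <- fdf$force_N
    attr(frc, "time_s") <- fdf$time_s
    trials[[i]] <- structure(list(
      trial_id = row$trial_id, subject_id = row$subject_id,
      speed_kmh = row$speed_kmh, body_mass_kg = row$body_mass_kg,
      angles = ang, force = frc
    ), class = "gait_trial")
  }
  list(trials = trials, manifest = manifest)
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf("Gait trial %s (%s): %g km/h, %.1f kg, %d angle samples @200 Hz, %d force samples @1000 Hz\n",
              x$trial_id, x$subject_id, x$speed_kmh, x$body_mass_kg,
              nrow(x$angles), length(x$force)))
  invisible(x)
}
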