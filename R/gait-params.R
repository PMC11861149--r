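#' Allowed nominal running speeds (km/h)
#'
#' The treadmill/overground protocol emulated by the generator uses five
#' nominal speeds. All speed arguments in the package are validated against
#' this set.
#' @export
GAIT_SPEEDS <- c(8, 10, 12, 14, 16)

#' Fixed channel layout: 3 joints x 3 anatomical planes
#'
#' Joint-major ordering (ankle, hip, knee) with plane order sagittal,
#' frontal, transversal. Every design matrix in the package uses subsets of
#' this layout in this order.
#' @export
channel_layout <- function() {
  data.frame(
    joint = rep(c("ankle", "hip", "knee"), each = 3),
    plane = rep(c("sagittal", "frontal", "transversal"), times = 3),
    stringsAsFactors = FALSE
  )
}

channel_names <- function(layout = channel_layout()) {
  paste(layout$joint, layout$plane, sep = "_")
}

# Half-cycle cosine basis coefficients for the 9 angle channels at the
# reference speed of 12 km/h (degrees). theta(u) = a0 + sum_k ak cos(k pi u),
# u in [0,1] stance fraction. Sagittal channels carry the largest amplitudes,
# as in stance-phase running kinematics.
.angle_base_coeffs <- function() {
  m <- rbind(
    ankle_sagittal    = c(-2,    8, -14,  3,   1),
    ankle_frontal     = c( 2,    3,  -2,  0.5, 0),
    ankle_transversal = c(-1,    2,  -1.5, 0.5, 0),
    hip_sagittal      = c(20,   18,   2, -1,   0),
    hip_frontal       = c( 5,   -4,   2,  0,   0),
    hip_transversal   = c( 0,    3,  -1,  0,   0),
    knee_sagittal     = c(28,   -3, -14,  1,   0),
    knee_frontal      = c( 2,   -2,   1.5, 0,  0),
    knee_transversal  = c(-2,    2.5, -1, 0.5, 0)
  )
  colnames(m) <- paste0("a", 0:4)
  m
}

# Linear speed sensitivity of the basis coefficients (degrees per km/h away
# from 12 km/h). Makes the inputs speed-informative: sagittal excursions grow
# with speed, out-of-plane channels change slowly.
.angle_speed_slopes <- function() {
  m <- rbind(
    ankle_sagittal    = c(0,    0.4, -0.9,  0.1, 0),
    ankle_frontal     = c(0,    0.15, -0.1, 0,   0),
    ankle_transversal = c(0,    0.1, -0.1,  0,   0),
    hip_sagittal      = c(0.3,  0.8,  0.1,  0,   0),
    hip_frontal       = c(0,   -0.2,  0.1,  0,   0),
    hip_transversal   = c(0,    0.15, 0,    0,   0),
    knee_sagittal     = c(0.2, -0.2, -0.8,  0.1, 0),
    knee_frontal      = c(0,   -0.1,  0.1,  0,   0),
    knee_transversal  = c(0,    0.1,  0,    0,   0)
  )
  colnames(m) <- paste0("a", 0:4)
  m
}

#' Default joint-angle basis coefficients for a nominal speed
#'
#' Returns the 9 x 5 matrix of half-cycle cosine coefficients (columns
#' `a0`..`a4`, degrees) used by [generate_joint_angles()]. Coefficients vary
#' linearly with speed around the 12 km/h reference so that the angle
#' curves, and through them the coupled vGRF, are speed-informative.
#'
#' @param speed_kmh nominal speed, one of [GAIT_SPEEDS].
#' @return numeric matrix, rows in the fixed [channel_layout()] order.
#' @export
default_angle_basis <- function(speed_kmh) {
  check_speed(speed_kmh)
  .angle_base_coeffs() + (speed_kmh - 12) * .angle_speed_slopes()
}

check_speed <- function(speed_kmh) {
  if (length(speed_kmh) != 1 || !is.numeric(speed_kmh) ||
      !(speed_kmh %in% GAIT_SPEEDS)) {
    stop("invalid speed ", format(speed_kmh), " km/h; allowed speeds are ",
         paste(GAIT_SPEEDS, collapse = ", "), " km/h", call. = FALSE)
  }
  invisible(speed_kmh)
}

#' Parameters of one synthetic running-stance trial
#'
#' Bundles everything the generator needs for one trial: the nominal speed,
#' subject mass, stance duration, the two vGRF peak magnitudes (body
#' weights) and their timings (stance fractions), the angle-basis
#' coefficients, the angle-to-force coupling gain, and the noise levels.
#' Speed-dependent defaults: stance duration shortens with speed while both
#' vGRF peaks grow, the usual trend across 8-16 km/h.
#'
#' @param speed_kmh nominal speed in km/h, one of [GAIT_SPEEDS].
#' @param body_mass_kg subject body mass (kg), positive.
#' @param stance_duration_s stance duration (s); default `0.340 - 0.009 *
#'   speed_kmh`.
#' @param impact_peak_bw impact-peak magnitude in body weights; default
#'   `1.35 + 0.055 * speed_kmh`.
#' @param active_peak_bw active-peak magnitude in body weights; default
#'   `2.10 + 0.05 * speed_kmh`.
#' @param impact_peak_frac,active_peak_frac peak timings as stance fractions
#'   in (0, 1), impact strictly before active.
#' @param coupling_gain_bw gain (BW) of the quadratic ankle/knee sagittal
#'   coupling added to the double-peak template; set to 0 for a pure
#'   template.
#' @param noise_sd_angle per-sample Gaussian noise on angles (degrees).
#' @param noise_sd_force per-sample Gaussian noise on the force channel, in
#'   body weights.
#' @param angle_basis_coeffs optional 9 x 5 coefficient matrix overriding
#'   [default_angle_basis()].
#' @return object of class `gait_params`.
#' @export
gait_params <- function(speed_kmh = 12,
                        body_mass_kg = 72.5,
                        stance_duration_s = NULL,
                        impact_peak_bw = NULL,
                        active_peak_bw = NULL,
                        impact_peak_frac = 0.13,
                        active_peak_frac = 0.45,
                        coupling_gain_bw = 0.2,
                        noise_sd_angle = 0.5,
                        noise_sd_force = 0.02,
                        angle_basis_coeffs = NULL) {
  check_speed(speed_kmh)
  if (is.null(stance_duration_s)) stance_duration_s <- 0.340 - 0.009 * speed_kmh
  if (is.null(impact_peak_bw))    impact_peak_bw    <- 1.35 + 0.055 * speed_kmh
  if (is.null(active_peak_bw))    active_peak_bw    <- 2.10 + 0.05 * speed_kmh
  if (is.null(angle_basis_coeffs)) {
    angle_basis_coeffs <- default_angle_basis(speed_kmh)
  }
  stopifnot(
    is.numeric(body_mass_kg), body_mass_kg > 0,
    stance_duration_s > 0,
    impact_peak_bw >= 0, active_peak_bw >= 0,
    noise_sd_angle >= 0, noise_sd_force >= 0, coupling_gain_bw >= 0,
    is.matrix(angle_basis_coeffs), nrow(angle_basis_coeffs) == 9,
    ncol(angle_basis_coeffs) == 5
  )
  if (!(0 < impact_peak_frac && impact_peak_frac < active_peak_frac &&
        active_peak_frac < 1)) {
    stop("peak timings must satisfy 0 < impact_peak_frac < active_peak_frac < 1",
         call. = FALSE)
  }
  rownames(angle_basis_coeffs) <- channel_names()
  structure(list(
    speed_kmh = speed_kmh,
    body_mass_kg = body_mass_kg,
    stance_duration_s = stance_duration_s,
    impact_peak_bw = impact_peak_bw,
    active_peak_bw = active_peak_bw,
    impact_peak_frac = impact_peak_frac,
    active_peak_frac = active_peak_frac,
    coupling_gain_bw = coupling_gain_bw,
    noise_sd_angle = noise_sd_angle,
    noise_sd_force = noise_sd_force,
    angle_basis_coeffs = angle_basis_coeffs
  ), class = "gait_params")
}

#' @export
print.gait_params <- function(x, ...) {
  cat("Synthetic gait trial parameters\n")
  cat(sprintf("  speed %g km/h, mass %.1f kg, stance %.3f s\n",
              x$speed_kmh, x$body_mass_kg, x$stance_duration_s))
  cat(sprintf("  vGRF peaks: impact %.2f BW @ %.0f%%, active %.2f BW @ %.0f%%\n",
              x$impact_peak_bw, 100 * x$impact_peak_frac,
              x$active_peak_bw, 100 * x$active_peak_frac))
  cat(sprintf("  coupling gain %.2f BW; noise: angle %.2f deg, force %.3f BW\n",
              x$coupling_gain_bw, x$noise_sd_angle, x$noise_sd_force))
  invisible(x)
}
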