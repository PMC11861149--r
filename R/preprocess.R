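# Preprocessing chain: zero-phase Butterworth filtering, 10 N stance
# detection, time normalization to 101 stance-percent points, min-max
# scaling, and assembly of the seven joint/plane design matrices M1..M7.

#' Low-pass filter specification
#'
#' @param cutoff_hz cutoff frequency (Hz); must be below Nyquist.
#' @param sample_rate_hz sampling rate of the series (Hz).
#' @param order filter order, a positive even integer (default 4).
#' @param zero_phase apply the filter forward and backward (`filtfilt`),
#'   removing phase lag at the cost of squaring the amplitude response.
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(cutoff_hz, sample_rate_hz, order = 4,
                        zero_phase = TRUE) {
  stopifnot(order > 0, order %% 2 == 0, cutoff_hz > 0, sample_rate_hz > 0)
  if (cutoff_hz >= sample_rate_hz / 2) {
    stop("cutoff_hz must be below the Nyquist frequency (",
         sample_rate_hz / 2, " Hz)", call. = FALSE)
  }
  structure(list(cutoff_hz = cutoff_hz, sample_rate_hz = sample_rate_hz,
                 order = order, zero_phase = zero_phase),
            class = "filter_spec")
}

#' Butterworth low-pass filter a series
#'
#' Fourth-order (by default) Butterworth low-pass, applied zero-phase
#' (forward-backward) so peak timings are not lagged -- the convention for
#' biomechanical signals. DC gain is 1 and the output has the input's
#' length. The forward-backward pass squares the amplitude response, so the
#' effective attenuation is twice the single-pass attenuation in dB.
#'
#' @param x numeric series.
#' @param spec a [filter_spec()].
#' @return filtered series, attributes of `x` preserved.
#' @export
butterworth_lowpass <- function(x, spec) {
  stopifnot(inherits(spec, "filter_spec"), is.numeric(x), all(is.finite(x)))
  bf <- signal::butter(spec$order, spec$cutoff_hz / (spec$sample_rate_hz / 2),
                       type = "low")
  pad <- 6 * (max(length(bf$b), length(bf$a)) - 1)
  if (length(x) < pad + 2) {
    stop("series too short (", length(x), ") for the filter's padding (needs >= ",
         pad + 2, " samples)", call. = FALSE)
  }
  xv <- as.numeric(x)
  y <- if (spec$zero_phase) {
    n <- length(xv)
    # odd-reflection padding with steady-state initial conditions at both
    # passes keeps edge transients out of the series (constant in = constant
    # out, exactly)
    ext <- c(2 * xv[1] - xv[(pad + 1):2], xv, 2 * xv[n] - xv[(n - 1):(n - pad)])
    fwd <- filter_ss(bf$b, bf$a, ext)
    bwd <- rev(filter_ss(bf$b, bf$a, rev(fwd)))
    bwd[pad + seq_len(n)]
  } else {
    filter_ss(bf$b, bf$a, xv)
  }
  attributes(y) <- attributes(x)
  y
}

# One causal IIR pass initialized in the step steady state of the first
# sample, so a constant series passes through unchanged.
filter_ss <- function(b, a, x) {
  x0 <- x[1]
  dc <- sum(b) / sum(a)
  as.numeric(signal::filter(b, a, x,
                            init = rep(x0 * dc, length(a) - 1),
                            init.x = rep(x0, length(b) - 1)))
}

#' Detect the stance phase with the 10 N threshold rule
#'
#' Finds the first maximal window in which the force rises above
#' `threshold_n` and later returns to it: `start` is the first sample with
#' force strictly above the threshold, `end` the first subsequent sample at
#' or below it (half-open `[start, end)`, 0-based indices). Sub-threshold
#' dips shorter than `debounce_s` that are flanked by supra-threshold
#' samples are bridged so sensor chatter does not split the stance.
#'
#' @param force numeric force series (N).
#' @param threshold_n contact threshold (N), default 10.
#' @param sample_rate_hz sampling rate, used only to convert `debounce_s`.
#' @param debounce_s minimum dip duration treated as a real lift-off.
#' @return object of class `stance_window` with fields `start`, `end`
#'   (0-based, half-open) and logical `truncated` (TRUE when the force
#'   never returned below the threshold and the window was closed at the
#'   series end, with a warning).
#' @export
detect_stance <- function(force, threshold_n = 10, sample_rate_hz = 1000,
                          debounce_s = 0.005) {
  stopifnot(is.numeric(force), all(is.finite(force)))
  above <- as.numeric(force) > threshold_n
  if (!any(above)) stop("no stance found: force never exceeds ", threshold_n,
                        " N", call. = FALSE)
  d <- max(1L, round(debounce_s * sample_rate_hz))
  r <- rle(above)
  # bridge short interior dips (chatter), keeping leading/trailing silence
  if (length(r$lengths) > 2) {
    interior <- seq(2, length(r$lengths) - 1)
    fill <- interior[!r$values[interior] & r$lengths[interior] < d]
    r$values[fill] <- TRUE
    above <- inverse.rle(r)
    r <- rle(above)
  }
  start0 <- which(above)[1] - 1L                      # 0-based
  ends <- cumsum(r$lengths)
  run <- which(r$values & ends > start0)[1]
  end0 <- ends[run]                                    # 0-based exclusive
  truncated <- FALSE
  if (end0 >= length(force) && above[length(force)]) {
    truncated <- TRUE
    warning("force never returned below ", threshold_n,
            " N; stance window closed at the series end")
  }
  structure(list(start = start0, end = end0, truncated = truncated),
            class = "stance_window")
}

#' @export
print.stance_window <- function(x, ...) {
  cat(sprintf("Stance window [%d, %d) (0-based)%s\n", x$start, x$end,
              if (x$truncated) " [truncated]" else ""))
  invisible(x)
}

#' Extract the samples covered by a stance window
#'
#' @param x numeric series the window was detected on (or any series with
#'   the same indexing).
#' @param window a [detect_stance()] result.
#' @return the samples in `[start, end)`.
#' @export
stance_slice <- function(x, window) {
  stopifnot(inherits(window, "stance_window"))
  as.numeric(x)[(window$start + 1L):window$end]
}

#' Time-normalize a stance series to a fixed percentage grid
#'
#' Linearly interpolates the series onto `n_points` uniformly spaced stance
#' fractions (0..100% for the default 101 points). The first and last input
#' samples are preserved exactly; an input already on the target grid is
#' returned unchanged.
#'
#' @param x numeric series (length >= 2).
#' @param n_points number of output points, default 101.
#' @return numeric vector of length `n_points`.
#' @export
time_normalize <- function(x, n_points = 101) {
  x <- as.numeric(x)
  if (length(x) < 2) stop("time_normalize needs at least 2 samples",
                          call. = FALSE)
  stats::approx(x = seq(0, 1, length.out = length(x)), y = x,
                xout = seq(0, 1, length.out = n_points), method = "linear")$y
}

#' Min-max scale a matrix to the unit interval per feature
#'
#' `x' = (x - min) / (max - min)` per column. When `params` is omitted the
#' per-feature min/max are computed from `x` (training fold) so the output
#' lies in `[0, 1]`; when `params` is supplied (test fold) they are reused
#' and the output may exceed `[0, 1]` -- no clipping, so no information
#' leaks from test to train. Constant features are mapped to 0 with a
#' warning.
#'
#' @param x numeric matrix (or vector, treated as one column).
#' @param params optional parameters from a previous fit.
#' @return list with `x` (scaled matrix) and `params` (list with `min`,
#'   `max` per feature).
#' @export
minmax_fit_transform <- function(x, params = NULL) {
  x <- as.matrix(x)
  stopifnot(all(is.finite(x)))
  if (is.null(params)) {
    params <- list(min = apply(x, 2, min), max = apply(x, 2, max))
  }
  rng <- params$max - params$min
  const <- rng <= 0
  if (any(const)) {
    warning(sum(const), " constant feature(s) mapped to 0 (max == min)")
  }
  denom <- ifelse(const, 1, rng)
  xs <- sweep(x, 2, params$min, "-")
  xs <- sweep(xs, 2, denom, "/")
  xs[, const] <- 0
  list(x = xs, params = params)
}

#' Invert a min-max transform
#'
#' @param x scaled matrix.
#' @param params the `params` element returned by [minmax_fit_transform()].
#' @return matrix on the original scale (constant features are restored to
#'   their stored minimum).
#' @export
minmax_inverse <- function(x, params) {
  x <- as.matrix(x)
  rng <- params$max - params$min
  denom <- ifelse(rng <= 0, 0, rng)
  sweep(sweep(x, 2, denom, "*"), 2, params$min, "+")
}

# The seven input factorizations: which channels of the full joint x plane
# layout each design matrix uses.
DATASET_DEFS <- list(
  M1 = list(joints = c("ankle", "hip", "knee"),
            planes = c("sagittal", "frontal", "transversal")),
  M2 = list(joints = "ankle", planes = c("sagittal", "frontal", "transversal")),
  M3 = list(joints = "hip",   planes = c("sagittal", "frontal", "transversal")),
  M4 = list(joints = "knee",  planes = c("sagittal", "frontal", "transversal")),
  M5 = list(joints = c("ankle", "hip", "knee"), planes = "sagittal"),
  M6 = list(joints = c("ankle", "hip", "knee"), planes = "frontal"),
  M7 = list(joints = c("ankle", "hip", "knee"), planes = "transversal")
)

#' Preprocess one trial: filter, segment, time-normalize
#'
#' Applies the chain used throughout the package: the force channel is
#' low-pass filtered (default 10 Hz cutoff at 1000 Hz), the stance window is
#' detected on the filtered force with the 10 N rule, the angle channels are
#' low-pass filtered (default 20 Hz cutoff at 200 Hz) and cropped to the
#' stance window via the shared time axis, and everything is linearly
#' resampled to `n_points` stance-percent points. The force target is
#' converted to body weights (`force / (mass * g)`).
#'
#' @param trial a `gait_trial` (from [generate_gait_dataset()] or
#'   [read_gait_dataset()]).
#' @param force_filter,angle_filter [filter_spec()]s for the two channel
#'   types.
#' @param threshold_n stance threshold (N).
#' @param n_points points of the stance-percent grid.
#' @return list with `angles` (`n_points` x 9 matrix, degrees), `y_bw`
#'   (length-`n_points` vGRF in body weights), `window`, and the trial
#'   metadata; or `NULL` (with a message) when the trial cannot be
#'   processed (no stance, or too few angle samples in the window).
#' @export
preprocess_trial <- function(trial,
                             force_filter = filter_spec(10, 1000),
                             angle_filter = filter_spec(20, 200),
                             threshold_n = 10,
                             n_points = 101) {
  f_filt <- try(butterworth_lowpass(trial$force, force_filter), silent = TRUE)
  if (inherits(f_filt, "try-error")) {
    message("trial ", trial$trial_id, " dropped: ", attr(f_filt, "condition")$message)
    return(NULL)
  }
  win <- try(detect_stance(f_filt, threshold_n = threshold_n,
                           sample_rate_hz = force_filter$sample_rate_hz),
             silent = TRUE)
  if (inherits(win, "try-error")) {
    message("trial ", trial$trial_id, " dropped: ",
            attr(win, "condition")$message)
    return(NULL)
  }
  f_time <- attr(trial$force, "time_s")
  if (is.null(f_time)) {
    f_time <- (seq_along(trial$force) - 1) / force_filter$sample_rate_hz
  }
  t_start <- f_time[win$start + 1L]
  t_end <- f_time[win$end]  # time of the first sample past the window
  y_stance <- stance_slice(f_filt, win)

  a_time <- attr(trial$angles, "time_s")
  if (is.null(a_time)) {
    a_time <- (seq_len(nrow(trial$angles)) - 1) / angle_filter$sample_rate_hz
  }
  keep <- a_time >= t_start & a_time < t_end
  if (sum(keep) < 2) {
    message("trial ", trial$trial_id,
            " dropped: fewer than 2 angle samples inside the stance window")
    return(NULL)
  }
  ang_out <- matrix(NA_real_, n_points, 9,
                    dimnames = list(NULL, channel_names()))
  for (j in seq_len(9)) {
    ch <- try(butterworth_lowpass(trial$angles[, j], angle_filter),
              silent = TRUE)
    if (inherits(ch, "try-error")) {
      message("trial ", trial$trial_id, " dropped: angle channel ",
              colnames(trial$angles)[j], " unfilterable")
      return(NULL)
    }
    ang_out[, j] <- time_normalize(ch[keep], n_points)
  }
  list(
    trial_id = trial$trial_id, subject_id = trial$subject_id,
    speed_kmh = trial$speed_kmh, body_mass_kg = trial$body_mass_kg,
    window = win,
    angles = ang_out,
    y_bw = time_normalize(y_stance, n_points) / (trial$body_mass_kg * GRAVITY)
  )
}

#' Assemble the seven design matrices M1..M7
#'
#' Runs [preprocess_trial()] on every trial and stacks the results into the
#' seven joint/plane factorizations: M1 uses all 9 channels (909 columns at
#' the default 101 points), M2/M3/M4 one joint on all planes, M5/M6/M7 all
#' joints on one plane (303 columns each). Features are flattened
#' channel-major (all 101 points of channel 1, then channel 2, ...) in the
#' fixed joint-major channel order; targets are the 101-point vGRF curves in
#' body weights. Trials that fail preprocessing are dropped with a message.
#'
#' @param trials list of `gait_trial` objects.
#' @param ... passed to [preprocess_trial()].
#' @return named list of `grf_design` objects with fields `name`, `X`, `y`,
#'   `channel_layout`, `trial_id`, `speed_kmh`, `body_mass_kg`, `n_points`.
#' @export
assemble_designs <- function(trials, ...) {
  pp <- lapply(trials, preprocess_trial, ...)
  kept <- !vapply(pp, is.null, TRUE)
  if (!any(kept)) stop("no trials survived preprocessing", call. = FALSE)
  if (any(!kept)) {
    message(sum(!kept), "/", length(trials), " trials dropped during preprocessing")
  }
  pp <- pp[kept]
  n <- length(pp)
  n_points <- length(pp[[1]]$y_bw)
  layout <- channel_layout()
  ch_names <- channel_names(layout)

  full_X <- matrix(NA_real_, n, 9 * n_points)
  y <- matrix(NA_real_, n, n_points)
  for (i in seq_len(n)) {
    full_X[i, ] <- as.numeric(pp[[i]]$angles)  # column-major = channel-major
    y[i, ] <- pp[[i]]$y_bw
  }
  colnames(full_X) <- paste(rep(ch_names, each = n_points),
                            sprintf("pct%03d", seq_len(n_points) - 1),
                            sep = "_")
  colnames(y) <- sprintf("y_pct%03d", seq_len(n_points) - 1)
  meta <- list(
    trial_id = vapply(pp, `[[`, "", "trial_id"),
    speed_kmh = vapply(pp, `[[`, 0, "speed_kmh"),
    body_mass_kg = vapply(pp, `[[`, 0, "body_mass_kg")
  )
  out <- lapply(names(DATASET_DEFS), function(nm) {
    def <- DATASET_DEFS[[nm]]
    sel <- which(layout$joint %in% def$joints & layout$plane %in% def$planes)
    cols <- as.vector(vapply(sel, function(ch) {
      (ch - 1L) * n_points + seq_len(n_points)
    }, integer(n_points)))
    structure(list(
      name = nm,
      X = full_X[, cols, drop = FALSE],
      y = y,
      channel_layout = layout[sel, , drop = FALSE],
      trial_id = meta$trial_id,
      speed_kmh = meta$speed_kmh,
      body_mass_kg = meta$body_mass_kg,
      n_points = n_points
    ), class = "grf_design")
  })
  names(out) <- names(DATASET_DEFS)
  out
}

#' @export
print.grf_design <- function(x, ...) {
  cat(sprintf("Design %s: %d trials x %d features (%d channels x %d points), targets %d x %d (BW)\n",
              x$name, nrow(x$X), ncol(x$X), nrow(x$channel_layout),
              x$n_points, nrow(x$y), ncol(x$y)))
  cat("  channels:", paste(paste(x$channel_layout$joint,
                                 x$channel_layout$plane, sep = "/"),
                           collapse = ", "), "\n")
  invisible(x)
}
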