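#' Preprocessing configuration
#'
#' Settings for the two preprocessing stages applied to every joint
#' trajectory before segmentation: cubic resampling of the jittered native
#' frame stream onto a uniform grid, then a low-pass Butterworth filter.
#'
#' @param target_rate Uniform resampling rate in Hz. Default 50.
#' @param filter_order Butterworth order. Default 3.
#' @param cutoff Low-pass cutoff in Hz. Default 5. Must be below the Nyquist
#'   rate `target_rate/2`.
#' @param zero_phase Apply the filter forward and backward so event instants
#'   carry no phase lag (default `TRUE`). The effective magnitude response is
#'   then `|H(f)|^2`.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(target_rate = 50, filter_order = 3, cutoff = 5,
                              zero_phase = TRUE) {
  stopifnot(target_rate > 0, filter_order >= 1)
  if (cutoff >= target_rate / 2)
    stop("cutoff must be below Nyquist (", target_rate / 2, " Hz)", call. = FALSE)
  structure(list(target_rate = target_rate, filter_order = filter_order,
                 cutoff = cutoff, zero_phase = zero_phase),
            class = "preprocess_config")
}

#' Resample all joint trajectories onto a uniform grid
#'
#' Interpolates each coordinate of each joint with a cubic spline
#' (`stats::splinefun`, `"fmm"` boundary conditions, exact on cubic
#' polynomials) evaluated on the uniform grid
#' `t_first + k / target_rate`, `k = 0, 1, ...`, spanning the trial.
#'
#' @param traj A [skeleton_trajectory_set] with at least 4 frames.
#' @param config A [preprocess_config].
#' @return A `skeleton_trajectory_set` on the uniform grid; the element
#'   `uniform_rate` records the grid rate for downstream stages.
#' @export
resample_uniform <- function(traj, config = preprocess_config()) {
  t <- traj$times
  if (length(t) < 4L) stop("need at least 4 samples to resample", call. = FALSE)
  if (anyDuplicated(t)) stop("duplicate timestamps", call. = FALSE)
  h <- 1 / config$target_rate
  grid <- t[1L] + h * (0:floor((t[length(t)] - t[1L]) / h))
  joints <- lapply(traj$joints, function(m) {
    out <- matrix(NA_real_, length(grid), 3L,
                  dimnames = list(NULL, c("x", "y", "z")))
    for (k in 1:3)
      out[, k] <- stats::splinefun(t, m[, k], method = "fmm")(grid)
    out
  })
  out <- skeleton_trajectory_set(traj$trial_id, grid, joints,
                                 system = traj$system,
                                 fps_nominal = traj$fps_nominal,
                                 rebase = FALSE)
  out$load_report <- traj$load_report
  out$uniform_rate <- config$target_rate
  out
}

# Zero-phase IIR pass with odd-reflection edge padding: the signal is
# extended at both ends by its point reflection, filtered forward and
# backward, and the pad discarded. Each pass removes the leading value first
# so the filter's zero initial state matches the signal (constants then pass
# exactly, with no startup step transient); the reflection suppresses the
# remaining slope transients near the trial edges.
filtfilt_reflect <- function(b, a, x) {
  n <- length(x)
  p <- min(n - 1L, max(24L, 9L * (length(a) - 1L)))
  xp <- c(2 * x[1L] - x[(p + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - p)])
  one_pass <- function(z) {
    as.numeric(signal::filter(b, a, z - z[1L])) + z[1L]
  }
  y <- one_pass(xp)
  y <- rev(one_pass(rev(y)))
  y[(p + 1L):(p + n)]
}

#' Low-pass filter all joint trajectories
#'
#' Applies a Butterworth low-pass of the configured order and cutoff to every
#' coordinate. With `zero_phase = TRUE` the filter runs forward and backward
#' (odd-reflection padding at the edges), so gait-event instants are not
#' biased by a phase lag; attenuation is then `|H(f)|^2`.
#'
#' @param traj A uniformly resampled [skeleton_trajectory_set]
#'   (see [resample_uniform()]).
#' @param config A [preprocess_config].
#' @return The filtered `skeleton_trajectory_set`.
#' @export
lowpass_filter <- function(traj, config = preprocess_config()) {
  t <- traj$times
  dt <- diff(t)
  if (length(t) < 2L || max(abs(dt - dt[1L])) > 1e-9 * max(dt[1L], 1))
    stop("non-uniform sampling: resample first", call. = FALSE)
  rate <- 1 / dt[1L]
  if (config$cutoff >= rate / 2)
    stop("cutoff at or above Nyquist", call. = FALSE)
  if (length(t) <= 3L * config$filter_order)
    stop("signal too short for filter order", call. = FALSE)
  bf <- signal::butter(config$filter_order, config$cutoff / (rate / 2), "low")
  apply_f <- function(x) {
    if (config$zero_phase) filtfilt_reflect(bf$b, bf$a, x)
    else as.numeric(signal::filter(bf$b, bf$a, x))
  }
  traj$joints <- lapply(traj$joints, function(m) {
    for (k in 1:3) m[, k] <- apply_f(m[, k])
    m
  })
  traj$filtered <- TRUE
  traj
}

#' Digital Butterworth magnitude response
#'
#' Magnitude of the bilinear-transform Butterworth low-pass at frequency `f`,
#' `1 / sqrt(1 + (tan(pi f / fs) / tan(pi fc / fs))^(2 n))`. For the
#' zero-phase (forward-backward) application square this value.
#'
#' @param f Frequency in Hz (vectorized).
#' @param rate Sampling rate in Hz.
#' @param cutoff Cutoff in Hz.
#' @param order Filter order.
#' @return Magnitude gain(s) in (0, 1].
#' @export
butter_gain <- function(f, rate = 50, cutoff = 5, order = 3) {
  1 / sqrt(1 + (tan(pi * f / rate) / tan(pi * cutoff / rate))^(2 * order))
}
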