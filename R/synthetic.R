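#' Synthetic gait configuration
#'
#' Parameters of the skeletal-gait simulator. Defaults describe the capture
#' geometry of a frontal RGB-D camera on a short walkway: the subject enters
#' tracking range beyond 5 m depth and walks toward the camera at 30 fps with
#' timestamp jitter and millimeter-scale joint noise.
#'
#' Stance is parameterized operationally, matching the ankle-stationarity
#' definition used by the segmentation stage: `duty_factor` is the fraction
#' of the cycle during which the ankle's depth velocity stays below the
#' motion gate (`threshold * analysis_rate`, 1 m/s by default). The swing
#' follows a minimum-jerk profile (`10u^3 - 15u^4 + 6u^5`) whose motion
#' window is widened symmetrically so the gate is crossed exactly at the
#' configured stance boundaries; the sub-gate tails model the slow ankle
#' roll/heel-rise near contact and lift. Set `calibrate_threshold = FALSE`
#' for the purely kinematic variant (motion window equal to the swing
#' window), in which the detector fires a few samples inside the swing.
#'
#' @param stride_length Stride length in m.
#' @param stride_time Stride (cycle) time in s.
#' @param duty_factor Stance fraction of the cycle, in (0.5, 0.8).
#' @param start_depth Depth (m) of the leading ankle's first plateau.
#'   Default 5.5.
#' @param stop_depth Depth (m) the ankles may not pass. Default 1.0.
#' @param v_amplitude Vertical CoM sine amplitude in m (half peak-to-peak),
#'   two cycles per stride.
#' @param ml_amplitude Lateral CoM sine amplitude in m (half peak-to-peak),
#'   one cycle per stride.
#' @param asymmetry List with `step_ratio` (affected/unaffected step split;
#'   the left side is the affected one) and `stance_ratio` (scales the left
#'   duty factor). Both 1 for symmetric gait.
#' @param fps Nominal camera frame rate in Hz. Default 30.
#' @param timestamp_jitter_sd SD (s) of Gaussian frame-timestamp jitter.
#'   Default 0.002.
#' @param noise_sd SD (m) of iid Gaussian noise per joint coordinate.
#'   Default 0.003, within reported body-tracking jitter magnitudes.
#' @param seed Integer seed; identical seeds give bitwise-identical streams.
#' @param calibrate_threshold See above. Default `TRUE`.
#' @param analysis_rate,threshold The segmentation grid rate (Hz) and depth
#'   threshold (m) the calibration targets. Defaults 50 and 0.02.
#' @return A list of class `synthetic_gait_config`.
#' @export
synthetic_gait_config <- function(stride_length = 1.40, stride_time = 1.02,
                                  duty_factor = 0.60,
                                  start_depth = 5.5, stop_depth = 1.0,
                                  v_amplitude = 0.0225, ml_amplitude = 0.021,
                                  asymmetry = list(step_ratio = 1, stance_ratio = 1),
                                  fps = 30, timestamp_jitter_sd = 0.002,
                                  noise_sd = 0.003, seed = NULL,
                                  calibrate_threshold = TRUE,
                                  analysis_rate = 50, threshold = 0.02) {
  stopifnot(stride_length > 0, stride_time > 0,
            duty_factor > 0.5, duty_factor < 0.8,
            start_depth > stop_depth, stop_depth > 0,
            fps > 0, noise_sd >= 0, timestamp_jitter_sd >= 0)
  if (is.null(asymmetry$step_ratio)) asymmetry$step_ratio <- 1
  if (is.null(asymmetry$stance_ratio)) asymmetry$stance_ratio <- 1
  stopifnot(asymmetry$step_ratio > 0, asymmetry$stance_ratio > 0)
  structure(list(stride_length = stride_length, stride_time = stride_time,
                 duty_factor = duty_factor, start_depth = start_depth,
                 stop_depth = stop_depth, v_amplitude = v_amplitude,
                 ml_amplitude = ml_amplitude, asymmetry = asymmetry,
                 fps = fps, timestamp_jitter_sd = timestamp_jitter_sd,
                 noise_sd = noise_sd, seed = seed,
                 calibrate_threshold = calibrate_threshold,
                 analysis_rate = analysis_rate, threshold = threshold),
            class = "synthetic_gait_config")
}

#' Preset configurations for healthy and hemiplegic gait
#'
#' Central stride length/time, stance fraction and CoM sway amplitudes of the
#' two study populations (reference-system group means): healthy gait at
#' 1.40 m / 1.02 s strides with ~60% stance and ~42/45 mm ML/V peak-to-peak
#' sway; hemiplegic gait at 0.76 m / 1.62 s with ~67% stance, enlarged
#' lateral sway (~91 mm peak-to-peak), reduced vertical sway and a 0.8
#' affected-to-unaffected step-length ratio.
#'
#' @param name `"healthy"` or `"hemiplegic"`.
#' @param ... Overrides passed on to [synthetic_gait_config()].
#' @return A `synthetic_gait_config`.
#' @export
gait_preset <- function(name = c("healthy", "hemiplegic"), ...) {
  name <- match.arg(name)
  args <- if (name == "healthy")
    list(stride_length = 1.40, stride_time = 1.02, duty_factor = 0.60,
         ml_amplitude = 0.021, v_amplitude = 0.0225,
         asymmetry = list(step_ratio = 1, stance_ratio = 1))
  else
    list(stride_length = 0.76, stride_time = 1.62, duty_factor = 0.67,
         ml_amplitude = 0.046, v_amplitude = 0.014,
         asymmetry = list(step_ratio = 0.8, stance_ratio = 1))
  over <- list(...)
  args[names(over)] <- over
  do.call(synthetic_gait_config, args)
}

# Minimum-jerk position profile on [0, 1].
minjerk <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u^3 * (10 - 15 * u + 6 * u^2)
}

# Creep margins (e_on before foot off, e_off after contact) such that the
# comparator displacement |d(t) - d(t - h)| crosses the threshold half a
# sample BEFORE each configured stance boundary: the first supra-threshold
# grid sample then falls within +-h/2 of the boundary regardless of grid
# offset. Both conditions reduce to placing the h-wide displacement window
# whose content equals the threshold at a common center distance c from the
# window edge: e_on = c + h, e_off = c - h, W = S + 2c.
solve_creep <- function(L, S, threshold, h, duty_time) {
  disp_at <- function(cc) {
    W <- S + 2 * cc
    L * (minjerk((cc + h / 2) / W) - minjerk((cc - h / 2) / W)) - threshold
  }
  uncalibrated <- list(e_on = 0, e_off = 0, calibrated = FALSE)
  lo <- h
  if (disp_at(lo) > 0)       # gate crossed within the first comparator window
    return(list(e_on = h, e_off = 0, calibrated = TRUE))
  # disp_at is unimodal in cc (the probe point moves toward mid-swing while
  # the widening window slows the whole swing); take the smallest root. Slow
  # gaits for which the swing cannot stay above the gate for its full
  # configured duration are left uncalibrated: the threshold rule then fires
  # inside the kinematic swing, and the operational ground truth records
  # where (the stance overestimation real slow walkers produce).
  grid <- seq(lo, max(2 * S, 0.5 * duty_time), length.out = 400L)
  vals <- vapply(grid, disp_at, numeric(1))
  k <- which(vals > 0)[1L]
  if (is.na(k)) return(uncalibrated)
  cc <- stats::uniroot(disp_at, c(grid[k - 1L], grid[k]), tol = 1e-12)$root
  if (2 * cc + h >= 0.95 * duty_time) return(uncalibrated)
  list(e_on = cc + h, e_off = cc - h, calibrated = TRUE)
}

# Per-side continuous ankle-depth model. Contacts at `contacts` (first entry
# is the virtual pre-trial contact one cycle early), plateau depths
# `plateaus`; each transition into contact j spans
# [contacts[j] - S - e_on, contacts[j] + e_off].
make_depth_fun <- function(contacts, plateaus, L, S, e_on, e_off) {
  W <- S + e_on + e_off
  ws <- contacts[-1L] - S - e_on   # window starts, one per transition
  function(t) {
    i <- findInterval(t, ws)
    d <- numeric(length(t))
    pre <- i == 0L
    d[pre] <- plateaus[1L]
    act <- !pre
    ia <- i[act]
    u <- (t[act] - ws[ia]) / W
    d[act] <- plateaus[ia] - L * minjerk(u)
    d
  }
}

# Vertical foot-lift bump during the motion window (sin^2 arch).
make_lift_fun <- function(contacts, S, e_on, e_off, lift = 0.05) {
  W <- S + e_on + e_off
  ws <- contacts[-1L] - S - e_on
  function(t) {
    i <- findInterval(t, ws)
    y <- numeric(length(t))
    act <- i > 0L
    u <- (t[act] - ws[i[act]]) / W
    u[u > 1] <- 1
    y[act] <- lift * sin(pi * u)^2
    y
  }
}

# Total time two stance interval sets overlap inside [a, b).
overlap_in_cycle <- function(int1, int2, a, b) {
  tot <- 0
  for (i in seq_len(nrow(int1))) for (j in seq_len(nrow(int2))) {
    lo <- max(int1[i, 1], int2[j, 1], a)
    hi <- min(int1[i, 2], int2[j, 2], b)
    if (hi > lo) tot <- tot + (hi - lo)
  }
  tot
}

#' Simulate a skeletal walking trial with known ground truth
#'
#' Generates an RGB-D-style skeleton stream of a subject walking toward the
#' camera: per-ankle depth alternates stance plateaus with minimum-jerk swing
#' transitions advancing one stride length; the hip joints translate at the
#' mean walking speed with a one-cycle lateral and a two-cycle vertical
#' sinusoid; frames are sampled at the nominal rate with Gaussian timestamp
#' jitter and iid Gaussian joint noise. The left side is the affected side
#' under asymmetry: contralateral contacts split the cycle (in time and
#' depth) as `step_ratio : 1`, and the left duty factor is scaled by
#' `stance_ratio`.
#'
#' Joints emitted: both ankles, hips and feet, plus `PELVIS` (hip midpoint)
#' for schema completeness.
#'
#' @param config A [synthetic_gait_config] or [gait_preset()].
#' @param n_strides Number of strides per leg (>= 2). If the walk would pass
#'   `stop_depth` mid-stride the trial is truncated with a warning.
#' @param trial_id Identifier stamped on the stream.
#' @return An object of class `synthetic_gait_trial`: list with `trajectory`
#'   (a [skeleton_trajectory_set]), `truth` (list with `events`, `params`,
#'   `com`, `creep`, `duration`) and `config`. Ground-truth `events` hold the
#'   side, kind, time and model depth of every detectable phase transition;
#'   `params` holds the per-cycle true values of all eight gait parameters;
#'   `com` the per-cycle true CoM excursions in mm.
#' @export
simulate_walk <- function(config = synthetic_gait_config(), n_strides = 4,
                          trial_id = "synthetic") {
  stopifnot(inherits(config, "synthetic_gait_config"))
  if (n_strides < 2) stop("need n_strides >= 2", call. = FALSE)
  L <- config$stride_length; T <- config$stride_time
  rho <- config$asymmetry$step_ratio
  d_R <- config$duty_factor
  d_L <- config$duty_factor * config$asymmetry$stance_ratio
  if (d_L <= 0.5 || d_L >= 0.95)
    stop("asymmetric left duty factor out of range", call. = FALSE)
  phi <- T * rho / (1 + rho)        # temporal split: left contact after right
  delta <- L * rho / (1 + rho)      # spatial split: left-leading step length

  n_max <- floor((config$start_depth - config$stop_depth - delta) / L)
  if (n_strides > n_max) {
    if (n_max < 2)
      stop("depth span too short for 2 strides at this stride length",
           call. = FALSE)
    warning("walk would pass stop_depth mid-stride: truncated to ",
            n_max, " strides")
    n_strides <- n_max
  }

  S_R <- (1 - d_R) * T; S_L <- (1 - d_L) * T
  h_an <- 1 / config$analysis_rate
  none <- list(e_on = 0, e_off = 0)
  e_R <- if (config$calibrate_threshold)
    solve_creep(L, S_R, config$threshold, h_an, d_R * T) else none
  e_L <- if (config$calibrate_threshold)
    solve_creep(L, S_L, config$threshold, h_an, d_L * T) else none

  # lead-in long enough that the stance run before the first detectable
  # swing onset survives debouncing on both sides
  t_lead <- max(S_R + e_R$e_on, S_L + e_L$e_on) + 0.1 * T
  # contacts: first entry is the virtual pre-trial contact one cycle early
  c_R <- t_lead + T * (-1:n_strides)
  c_L <- t_lead + phi + T * (-1:n_strides)
  P_R <- config$start_depth - L * (-1:n_strides)
  P_L <- config$start_depth - delta - L * (-1:n_strides)
  dur <- t_lead + phi + n_strides * T + 0.35 * T

  depth_R <- make_depth_fun(c_R, P_R, L, S_R, e_R$e_on, e_R$e_off)
  depth_L <- make_depth_fun(c_L, P_L, L, S_L, e_L$e_on, e_L$e_off)
  lift_R <- make_lift_fun(c_R, S_R, e_R$e_on, e_R$e_off)
  lift_L <- make_lift_fun(c_L, S_L, e_L$e_on, e_L$e_off)

  v_mean <- L / T
  z0 <- config$start_depth + (L - delta) / 2
  hip_z <- function(t) z0 - v_mean * t
  hip_y <- function(t) 0.92 + config$v_amplitude * sin(4 * pi * t / T)
  hip_x <- function(t) config$ml_amplitude * sin(2 * pi * t / T)

  # ground truth -------------------------------------------------------------
  # Event times are the operational (detectable) instants: where the
  # continuous noiseless model's displacement over one analysis-rate sample
  # crosses the threshold. Under calibration these sit half a sample before
  # the configured kinematic stance boundaries; for gaits too slow for
  # calibration they sit inside the kinematic swing, exactly as the threshold
  # rule will report them.
  crossings <- function(W) {
    g <- function(dt) L * (minjerk(dt / W) - minjerk((dt - h_an) / W)) -
      config$threshold
    mid <- (W + h_an) / 2
    if (g(mid) <= 0)
      stop("motion gate never crossed during swing", call. = FALSE)
    list(r1 = stats::uniroot(g, c(0, mid), tol = 1e-12)$root,
         r2 = stats::uniroot(g, c(mid, W + h_an), tol = 1e-12)$root)
  }
  cr_R <- crossings(S_R + e_R$e_on + e_R$e_off)
  cr_L <- crossings(S_L + e_L$e_on + e_L$e_off)

  ev <- list()
  side_info <- list(
    left = list(cs = c_L, S = S_L, e = e_L, cr = cr_L, dfun = depth_L),
    right = list(cs = c_R, S = S_R, e = e_R, cr = cr_R, dfun = depth_R))
  stance_ints <- list()
  for (s in names(side_info)) {
    si <- side_info[[s]]
    ws <- si$cs[-1L] - si$S - si$e$e_on     # window starts
    x1 <- ws + si$cr$r1                     # operational swing onsets
    x2 <- ws + si$cr$r2                     # operational stance onsets
    for (j in seq_along(ws)) {
      if (x1[j] > 0 && x1[j] < dur) ev[[length(ev) + 1L]] <-
          data.frame(side = s, kind = "swing_onset", time = x1[j],
                     depth = si$dfun(x1[j]), stringsAsFactors = FALSE)
      if (x2[j] > 0 && x2[j] < dur) ev[[length(ev) + 1L]] <-
          data.frame(side = s, kind = "stance_onset", time = x2[j],
                     depth = si$dfun(x2[j]), stringsAsFactors = FALSE)
    }
    # operational stance intervals (incl. before first and after last swing)
    lo <- c(0, x2)
    hi <- c(x1, dur)
    keep <- hi > lo & hi > 0 & lo < dur
    stance_ints[[s]] <- cbind(pmax(lo[keep], 0), pmin(hi[keep], dur))
  }
  events <- do.call(rbind, ev)
  events <- events[order(events$time), , drop = FALSE]
  rownames(events) <- NULL

  params <- list()
  for (s in names(side_info)) {
    si <- side_info[[s]]
    contacts <- events[events$side == s & events$kind == "stance_onset", ,
                       drop = FALSE]
    offs <- events[events$side == s & events$kind == "swing_onset", ,
                   drop = FALSE]
    other <- events[events$side != s & events$kind == "stance_onset", ,
                    drop = FALSE]
    d_s <- if (s == "left") d_L else d_R
    if (nrow(contacts) < 2L) next
    for (k in seq_len(nrow(contacts) - 1L)) {
      a <- contacts$time[k]; b <- contacts$time[k + 1L]
      ds <- overlap_in_cycle(stance_ints$left, stance_ints$right, a, b)
      foot_off <- offs$time[offs$time > a & offs$time < b]
      prev <- other[other$time < b - 1e-9 & other$time > a - 1e-9, , drop = FALSE]
      step_len <- step_tim <- NA_real_
      if (nrow(prev)) {
        p <- prev[nrow(prev), ]
        step_len <- abs(contacts$depth[k + 1L] - p$depth)
        step_tim <- b - p$time
      }
      params[[length(params) + 1L]] <- data.frame(
        side = s, cycle = k, t_start = a, t_end = b,
        step_length = step_len, step_time = step_tim,
        stride_length = L, stride_time = T,
        double_support = ds,
        foot_off_pct = if (length(foot_off) == 1L)
          100 * (foot_off - a) / (b - a) else 100 * d_s,
        foot_off_pct_kinematic = 100 * d_s,
        walking_speed = L / T, cadence = 120 / T,
        stringsAsFactors = FALSE)
    }
  }
  params <- do.call(rbind, params)
  rownames(params) <- NULL
  com_truth <- data.frame(ap_mm = 1000 * L,
                          ml_mm = 2000 * config$ml_amplitude,
                          v_mm = 2000 * config$v_amplitude)

  # frame sampling -----------------------------------------------------------
  if (!is.null(config$seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
    }
    set.seed(config$seed)
  }
  n_frames <- floor(dur * config$fps) + 1L
  t <- (seq_len(n_frames) - 1L) / config$fps
  if (config$timestamp_jitter_sd > 0) {
    jit <- stats::rnorm(n_frames, 0, config$timestamp_jitter_sd)
    jit[1L] <- 0                       # recording clock starts at first frame
    t <- t + jit
    t <- cummax(t + 1e-9 * seq_len(n_frames))   # enforce strict monotonicity
  }

  half_w <- 0.09
  joints <- list(
    ANKLE_LEFT = cbind(-0.10, 0.08 + lift_L(t), depth_L(t)),
    ANKLE_RIGHT = cbind(0.10, 0.08 + lift_R(t), depth_R(t)),
    HIP_LEFT = cbind(hip_x(t) - half_w, hip_y(t), hip_z(t)),
    HIP_RIGHT = cbind(hip_x(t) + half_w, hip_y(t), hip_z(t)),
    FOOT_LEFT = cbind(-0.10, 0.03 + lift_L(t), depth_L(t) - 0.10),
    FOOT_RIGHT = cbind(0.10, 0.03 + lift_R(t), depth_R(t) - 0.10))
  joints$PELVIS <- (joints$HIP_LEFT + joints$HIP_RIGHT) / 2
  if (config$noise_sd > 0)
    joints <- lapply(joints, function(m)
      m + stats::rnorm(length(m), 0, config$noise_sd))

  traj <- skeleton_trajectory_set(trial_id, t, joints, system = "MAK",
                                  fps_nominal = config$fps, rebase = FALSE)
  structure(list(trajectory = traj,
                 truth = list(events = events, params = params,
                              com = com_truth,
                              creep = list(left = e_L, right = e_R),
                              duration = dur, n_strides = n_strides),
                 config = config),
            class = "synthetic_gait_trial")
}

#' @export
print.synthetic_gait_trial <- function(x, ...) {
  cat("synthetic gait trial: ", x$truth$n_strides, " strides/leg, ",
      length(x$trajectory$times), " frames, ",
      sprintf("%.2f", x$truth$duration), " s\n", sep = "")
  cat(sprintf("  stride %.2f m / %.2f s, duty %.2f, step ratio %.2f\n",
              x$config$stride_length, x$config$stride_time,
              x$config$duty_factor, x$config$asymmetry$step_ratio))
  invisible(x)
}

#' Paired measured/actual fixtures with known bias and correlation
#'
#' Builds a tidy method-comparison table for validating the agreement
#' statistics end to end: per-subject true parameter values are drawn around
#' the configured gait (between-subject coefficient of variation `sd_frac`),
#' the reference system reports them exactly (`actual`) and the test system
#' reports `bias * actual + noise` (`measured`). The implied true Pearson
#' correlation per parameter, `b * sd_a / sqrt(b^2 sd_a^2 + sd_e^2)`, is
#' returned alongside. A zero-noise pair of skeleton streams of the same walk
#' (reference exact, test with sensor noise) accompanies the table.
#'
#' @param config A [synthetic_gait_config].
#' @param systems_bias Named list per parameter (any of the eight parameter
#'   names) with elements `bias` (multiplicative, default 1) and `noise_sd`
#'   (additive SD on the measured value, default 0). Parameters not listed
#'   get bias 1, noise 0.
#' @param n_subjects Number of simulated subjects. Default 60.
#' @param sd_frac Between-subject SD as a fraction of the central value.
#'   Default 0.15.
#' @param group Group label stamped on the table. Default `"healthy"`.
#' @param seed Seed for the subject draws (defaults to `config$seed`).
#' @return List with `pairs` (data frame `parameter`, `group`, `subject`,
#'   `trial`, `measured`, `actual`), `true_r` (named vector), `reference` and
#'   `test` ([skeleton_trajectory_set]s of one example walk).
#' @export
emit_paired_trials <- function(config = synthetic_gait_config(),
                               systems_bias = list(), n_subjects = 60,
                               sd_frac = 0.15, group = "healthy",
                               seed = config$seed) {
  centres <- c(step_length = config$stride_length / 2,
               step_time = config$stride_time / 2,
               stride_length = config$stride_length,
               stride_time = config$stride_time,
               double_support = (2 * config$duty_factor - 1) * config$stride_time,
               foot_off_pct = 100 * config$duty_factor,
               walking_speed = config$stride_length / config$stride_time,
               cadence = 120 / config$stride_time)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
    }
    set.seed(seed)
  }
  rows <- list(); true_r <- numeric(0)
  for (p in names(centres)) {
    b <- 1; ns <- 0
    if (!is.null(systems_bias[[p]])) {
      if (!is.null(systems_bias[[p]]$bias)) b <- systems_bias[[p]]$bias
      if (!is.null(systems_bias[[p]]$noise_sd)) ns <- systems_bias[[p]]$noise_sd
    }
    sd_a <- sd_frac * centres[[p]]
    actual <- stats::rnorm(n_subjects, centres[[p]], sd_a)
    measured <- b * actual + stats::rnorm(n_subjects, 0, ns)
    true_r[p] <- b * sd_a / sqrt(b^2 * sd_a^2 + ns^2)
    rows[[p]] <- data.frame(parameter = p, group = group,
                            subject = seq_len(n_subjects), trial = 1L,
                            measured = measured, actual = actual,
                            stringsAsFactors = FALSE)
  }
  cfg_ref <- config; cfg_ref$noise_sd <- 0; cfg_ref$timestamp_jitter_sd <- 0
  ref <- simulate_walk(cfg_ref, n_strides = 2, trial_id = "reference")
  cfg_test <- config
  if (is.null(cfg_test$seed)) cfg_test$seed <- if (!is.null(seed)) seed else 1L
  test <- simulate_walk(cfg_test, n_strides = 2, trial_id = "test")
  list(pairs = do.call(rbind, rows), true_r = true_r,
       reference = ref$trajectory, test = test$trajectory)
}
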