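# Shared fixtures: all inputs are generated in code at test time.

# VGAP gate wide open so every simulated stride is analyzed (recovery-study
# geometry; the study's 1.5-4.5 m window is exercised separately).
wide_segmentation <- function(...) {
  segmentation_config(vgap_near = 0.2, vgap_far = 20, ...)
}

# Noise-free, jitter-free walk on a walkway long enough for n strides.
clean_walk <- function(preset = "healthy", n_strides = 4, ...) {
  simulate_walk(gait_preset(preset, noise_sd = 0, timestamp_jitter_sd = 0,
                            start_depth = 11, stop_depth = 1, ...),
                n_strides = n_strides)
}

noisy_walk <- function(preset = "healthy", n_strides = 4, seed = 1,
                       noise_sd = 0.003, ...) {
  simulate_walk(gait_preset(preset, noise_sd = noise_sd, seed = seed,
                            start_depth = 11, stop_depth = 1, ...),
                n_strides = n_strides)
}

# Wrap a scalar signal into a single-joint trajectory set (positions carried
# on the depth axis).
signal_set <- function(times, x, joint = "ANKLE_RIGHT") {
  m <- cbind(0, 0, x)
  skeleton_trajectory_set("sig", times, stats::setNames(list(m), joint),
                          rebase = FALSE)
}

# Absolute time error (s) from each ground-truth event to the nearest
# detected event of the same side and kind.
event_errors <- function(fit, truth) {
  errs <- numeric(0)
  for (s in c("left", "right")) for (k in c("stance_onset", "swing_onset")) {
    det <- fit$events$time[fit$events$side == s & fit$events$kind == k]
    tru <- truth$events$time[truth$events$side == s & truth$events$kind == k]
    if (!length(tru)) next
    errs <- c(errs, if (!length(det)) rep(Inf, length(tru))
              else vapply(tru, function(t) min(abs(det - t)), numeric(1)))
  }
  errs
}

# Least-squares amplitude of a sinusoid at frequency f in a sampled signal,
# edges trimmed to discard filter transients.
fitted_amplitude <- function(t, x, f, trim = 1) {
  keep <- t >= min(t) + trim & t <= max(t) - trim
  fit <- stats::lm(x[keep] ~ sin(2 * pi * f * t[keep]) + cos(2 * pi * f * t[keep]))
  sqrt(sum(stats::coef(fit)[2:3]^2))
}
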