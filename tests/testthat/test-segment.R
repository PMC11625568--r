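test_that("threshold rule labels stationary, moving and tied series", {
  t <- (0:49) / 50
  cst <- label_phases(rep(3, 50), t, "right")
  expect_true(all(cst$labels == 0L))
  ramp <- label_phases(3 - 0.03 * (0:49), t, "right")     # 0.03 m per sample
  expect_true(all(ramp$labels == 1L))
  # a delta of exactly the threshold is stance: motion needs strictly
  # greater. Tested with a binary-exact threshold (1/32 m) so the tie is a
  # true tie and not a rounding artifact.
  cfg <- segmentation_config(threshold = 1 / 32)
  tied <- label_phases(3 - (0:49) / 32, t, "right", cfg)
  expect_true(all(tied$labels == 0L))
  above <- label_phases(3 - (0:49) * (1 / 32 + 1e-9), t, "right", cfg)
  expect_true(all(above$labels == 1L))
  expect_error(label_phases(3, 0, "right"), "2 samples")
})

test_that("labels match a brute-force per-sample re-computation", {
  set.seed(21)
  for (rep in 1:30) {
    n <- 120
    depth <- 4 + cumsum(stats::rnorm(n, 0, 0.02))
    t <- (0:(n - 1)) / 50
    got <- label_phases(depth, t, "left", debounce = FALSE)$labels
    # independent naive oracle
    oracle <- integer(n)
    for (i in 2:n) oracle[i] <- if (abs(depth[i] - depth[i - 1]) > 0.02) 1L else 0L
    oracle[1] <- oracle[2]
    expect_identical(got, oracle)
    # pre-debounce labels are also exposed alongside debounced ones
    expect_identical(label_phases(depth, t, "left")$raw_labels, oracle)
  }
})

test_that("debounce removes short chatter runs", {
  depth <- c(rep(3, 20), 3 - 0.05 * (1:20), rep(2, 20))
  depth[10] <- 3.03   # single-sample blip inside stance
  t <- seq_along(depth) / 50
  lab <- label_phases(depth, t, "right")
  expect_true(all(lab$labels[1:18] == 0L))   # blip merged away
  raw <- label_phases(depth, t, "right", debounce = FALSE)$labels
  expect_true(any(raw[9:11] == 1L))          # but present pre-debounce
})

test_that("raising the threshold never decreases stance-labeled samples", {
  set.seed(9)
  depth <- 4 + cumsum(stats::rnorm(200, 0, 0.02))
  t <- (0:199) / 50
  stance <- vapply(c(0.005, 0.01, 0.02, 0.04, 0.08), function(th)
    sum(label_phases(depth, t, "left", segmentation_config(threshold = th),
                     debounce = FALSE)$labels == 0L), numeric(1))
  expect_true(all(diff(stance) >= 0))
})

test_that("events appear at phase transitions with side alternation", {
  t <- (0:5) / 50
  lab <- structure(list(side = "right", times = t, depth = rep(3, 6),
                        labels = c(0L, 0L, 1L, 1L, 0L, 0L)),
                   class = "phase_label_series")
  ev <- extract_events(right = lab)
  expect_equal(ev$kind, c("swing_onset", "stance_onset"))
  expect_equal(ev$index, c(3L, 5L))          # first samples of the new phases
  expect_equal(ev$time, t[c(3, 5)])
  all_stance <- structure(list(side = "left", times = t, depth = rep(3, 6),
                               labels = rep(0L, 6)),
                          class = "phase_label_series")
  expect_warning(ev0 <- extract_events(left = all_stance), "no phase transitions")
  expect_equal(nrow(ev0), 0L)
})

test_that("strides and steps follow the event geometry and the VGAP gate", {
  ev <- data.frame(
    side = c("right", "left", "right"),
    kind = "stance_onset",
    index = c(50L, 75L, 100L),
    time = c(1.0, 1.5, 2.0),
    depth = c(4.0, 3.5, 3.0), stringsAsFactors = FALSE)
  out <- suppressWarnings(build_strides_and_steps(ev, segmentation_config()))
  expect_equal(nrow(out$strides), 1L)
  expect_equal(out$strides$side, "right")
  expect_equal(out$strides$length, 1.0)
  expect_equal(out$strides$duration, 1.0)
  # the left contact splits the right stride into two steps
  expect_equal(nrow(out$steps), 2L)
  right_step <- out$steps[out$steps$side == "right", ]
  expect_equal(right_step$length, 0.5)
  expect_equal(right_step$duration, 0.5)

  # a stride ending nearer than the VGAP near bound is excluded
  ev$depth <- c(2.2, 1.7, 1.2)
  gated <- suppressWarnings(
    build_strides_and_steps(ev, segmentation_config(vgap_near = 1.5)))
  expect_equal(nrow(gated$strides), 0L)
  ungated <- suppressWarnings(
    build_strides_and_steps(ev, segmentation_config(vgap_near = 1.5),
                            gate_vgap = FALSE))
  expect_equal(nrow(ungated$strides), 1L)
})

test_that("phase structure is consistent on simulated gait", {
  tr <- clean_walk("healthy", 3)
  fit <- analyze_gait(tr, segmentation = wide_segmentation())
  for (s in c("left", "right")) {
    r <- rle(fit$labels[[s]]$labels)
    n_stance <- sum(r$values == 0L)
    n_swing <- sum(r$values == 1L)
    expect_lte(abs(n_stance - n_swing), 1L)
    # phase durations partition the trial
    dt <- diff(fit$labels[[s]]$times[1:2])
    expect_equal(sum(r$lengths) * dt,
                 length(fit$labels[[s]]$times) * dt)
  }
  # step lengths of opposite sides sum to the stride length
  steps <- fit$steps[order(fit$steps$t_end), ]
  for (i in which(steps$side[-1] != steps$side[-nrow(steps)]))
    expect_equal(steps$length[i] + steps$length[i + 1],
                 unique(fit$strides$length)[1], tolerance = 0.02)
})
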