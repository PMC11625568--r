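#' Analyze one walking trial end to end
#'
#' The main entry point: runs the full estimation pipeline on a skeletal
#' trajectory stream in the fixed stage order resample (uniform 50 Hz cubic)
#' -> low-pass filter (zero-phase 3rd-order 5 Hz Butterworth) -> ankle
#' stance/swing segmentation (2 cm depth-delta threshold) -> gait events ->
#' strides/steps inside the VGAP depth window -> spatio-temporal parameters
#' and per-cycle CoM excursions (hip-midpoint proxy). The analysis path
#' contains no randomness: identical input and configuration give identical
#' output.
#'
#' @param x A [skeleton_trajectory_set], a [synthetic_gait_trial], or a path
#'   to a JSON stream readable by [read_mak_json()].
#' @param preprocess A [preprocess_config].
#' @param segmentation A [segmentation_config].
#' @param pooling Pooling policy for the summary, see
#'   [aggregate_parameters()].
#' @param gate_vgap Apply the VGAP depth gate to strides and steps
#'   (default `TRUE`).
#' @return An object of class `gait_analysis`: list with `records` (one row
#'   per stride, all eight parameters), `summary` (pooled parameter table),
#'   `strides`, `steps`, `events`, `labels` (per-side `phase_label_series`),
#'   `com_excursions` and `com_summary`, `report` (dropped frames, excluded
#'   strides, warnings) and the configurations used. Methods: `print`,
#'   `summary`, `coef` (pooled parameter means), `plot` (segmentation view).
#' @examples
#' trial <- simulate_walk(gait_preset("healthy"), n_strides = 2)
#' fit <- analyze_gait(trial)
#' coef(fit)
#' @export
analyze_gait <- function(x, preprocess = preprocess_config(),
                         segmentation = segmentation_config(),
                         pooling = c("trial_mean", "stride"),
                         gate_vgap = TRUE) {
  pooling <- match.arg(pooling)
  if (is.character(x)) x <- read_mak_json(x)
  if (inherits(x, "synthetic_gait_trial")) x <- x$trajectory
  stopifnot(inherits(x, "skeleton_trajectory_set"))
  warn <- character(0)
  catch <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warn <<- c(warn, conditionMessage(w)); invokeRestart("muffleWarning")
  })
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed for trial '", x$trial_id, "': ",
           conditionMessage(e), call. = FALSE))
  }

  uni <- stage("resample", resample_uniform(x, preprocess))
  fil <- stage("filter", lowpass_filter(uni, preprocess))

  labs <- stage("segment", {
    lapply(c(left = "left", right = "right"), function(s) {
      j <- if (s == "left") "ANKLE_LEFT" else "ANKLE_RIGHT"
      label_phases(joint_axis_series(fil, j, "depth"), fil$times, side = s,
                   config = segmentation)
    })
  })
  events <- catch(stage("events", extract_events(labs$left, labs$right)))
  built <- catch(stage("strides",
                       build_strides_and_steps(events, segmentation,
                                               gate_vgap = gate_vgap)))
  n_raw <- nrow(build_strides_and_steps(events, segmentation,
                                        gate_vgap = FALSE)$strides)

  records <- stage("parameters",
                   gait_parameter_records(built$strides, built$steps,
                                          labs$left, labs$right, x$trial_id))

  com <- stage("com", com_from_hips(fil))
  exc <- catch(stage("com", excursions_per_cycle(com, built$strides)))

  structure(list(
    trial_id = x$trial_id,
    records = records,
    summary = if (nrow(records)) aggregate_parameters(records, pooling) else NULL,
    strides = built$strides, steps = built$steps, events = events,
    labels = labs, com = com, com_excursions = exc,
    com_summary = if (nrow(exc)) aggregate_excursions(exc) else NULL,
    report = list(frames_total = x$load_report$frames_total,
                  frames_dropped = x$load_report$frames_dropped,
                  strides_detected = n_raw,
                  strides_excluded_vgap = n_raw - nrow(built$strides),
                  warnings = warn),
    preprocess = preprocess, segmentation = segmentation,
    pooling = pooling),
    class = "gait_analysis")
}

#' @export
print.gait_analysis <- function(x, ...) {
  cat("Gait analysis of trial '", x$trial_id, "'\n", sep = "")
  cat("  ", nrow(x$strides), " strides (", x$report$strides_excluded_vgap,
      " excluded by VGAP gate), ", nrow(x$steps), " steps\n", sep = "")
  if (!is.null(x$summary)) {
    cat(sprintf("  walking speed %.2f m/s, cadence %.1f steps/min, stride %.2f m / %.2f s\n",
                x$summary$mean[x$summary$parameter == "walking_speed"],
                x$summary$mean[x$summary$parameter == "cadence"],
                x$summary$mean[x$summary$parameter == "stride_length"],
                x$summary$mean[x$summary$parameter == "stride_time"]))
  } else cat("  no strides detected\n")
  if (length(x$report$warnings))
    cat("  warnings:", paste(unique(x$report$warnings), collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.gait_analysis <- function(object, ...) {
  cat("Spatio-temporal parameters (pooled ", object$pooling, "):\n", sep = "")
  if (!is.null(object$summary)) print(object$summary, digits = 4)
  else cat("  none\n")
  if (!is.null(object$com_summary)) {
    cat("\nCoM excursions per gait cycle (mm):\n")
    print(object$com_summary, digits = 4)
  }
  invisible(object)
}

#' @export
coef.gait_analysis <- function(object, ...) {
  if (is.null(object$summary)) return(stats::setNames(numeric(0), character(0)))
  stats::setNames(object$summary$mean, object$summary$parameter)
}

#' @export
plot.gait_analysis <- function(x, ...) {
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  ll <- x$labels$left; rr <- x$labels$right
  graphics::plot(rr$times, rr$depth, type = "l", col = "darkgreen",
                 xlab = "time (s)", ylab = "ankle depth (m)",
                 main = paste("Trial", x$trial_id), ...)
  graphics::lines(ll$times, ll$depth, col = "blue", lty = 2)
  graphics::abline(h = c(x$segmentation$vgap_near, x$segmentation$vgap_far),
                   col = "grey60", lty = 3)
  graphics::legend("topright", c("right ankle", "left ankle", "VGAP"),
                   col = c("darkgreen", "blue", "grey60"),
                   lty = c(1, 2, 3), bty = "n", cex = 0.8)
  graphics::plot(rr$times, rr$labels, type = "s", col = "darkgreen",
                 ylim = c(-0.1, 1.1), xlab = "time (s)",
                 ylab = "phase (0 stance / 1 swing)")
  graphics::lines(ll$times, ll$labels + 0.02, type = "s", col = "blue", lty = 2)
  invisible(x)
}

#' Method-comparison report between two measurement systems
#'
#' Wraps [agreement_table()] into a report object mirroring the study layout:
#' one statistics block per parameter for the pooled data and per group, with
#' Bland-Altman panels available through `plot()`.
#'
#' @param pairs Tidy data frame with columns `parameter`, `measured`,
#'   `actual` and optionally `group`, `subject`, `trial`. Rows with missing
#'   measured or actual values are dropped with a count in the report.
#' @param min_pairs Minimum pairs per cell, see [agreement_table()].
#' @return An object of class `gait_agreement` with elements `table`,
#'   `pairs`, `dropped`. Methods: `print`, `summary`, `plot`.
#' @export
run_comparison <- function(pairs, min_pairs = 3L) {
  stopifnot(all(c("parameter", "measured", "actual") %in% names(pairs)))
  ok <- is.finite(pairs$measured) & is.finite(pairs$actual)
  dropped <- sum(!ok)
  if (dropped) warning(dropped, " incomplete pairs dropped")
  pairs <- pairs[ok, , drop = FALSE]
  if (!"group" %in% names(pairs)) {
    warning("no group labels: pooled-only output")
  }
  structure(list(table = agreement_table(pairs, min_pairs = min_pairs),
                 pairs = pairs, dropped = dropped),
            class = "gait_agreement")
}

#' @export
print.gait_agreement <- function(x, ...) {
  cat("Method comparison over", length(unique(x$table$parameter)),
      "parameters,", nrow(x$pairs), "pairs\n")
  show <- x$table[, c("group", "parameter", "n", "t_p", "accuracy_pct",
                      "pearson_r", "rmse")]
  print(show, digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
summary.gait_agreement <- function(object, ...) {
  print(object$table, digits = 4)
  invisible(object)
}

#' @export
plot.gait_agreement <- function(x, group = "all", ...) {
  tab <- x$table[x$table$group == group, , drop = FALSE]
  pars <- tab$parameter
  n <- length(pars)
  nc <- ceiling(sqrt(n))
  old <- graphics::par(mfrow = c(ceiling(n / nc), nc), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  sub <- if (group == "all") x$pairs else
    x$pairs[x$pairs$group == group, , drop = FALSE]
  for (p in pars) {
    cell <- sub[sub$parameter == p, , drop = FALSE]
    plot(bland_altman(cell$measured, cell$actual), main = p, ...)
  }
  invisible(x)
}
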