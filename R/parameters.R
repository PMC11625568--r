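#' Stride-level spatio-temporal metrics
#'
#' Adds walking speed and cadence to a stride table: speed is the ratio of
#' stride length to stride time, cadence the number of steps per minute
#' computed as 120 divided by the stride time (two steps per stride).
#'
#' @param strides Stride data frame from [build_strides_and_steps()].
#' @return The stride data frame with `walking_speed` (m/s) and `cadence`
#'   (steps/min) columns appended.
#' @export
stride_metrics <- function(strides) {
  if (any(strides$duration <= 0)) stop("stride with zero duration", call. = FALSE)
  strides$walking_speed <- strides$length / strides$duration
  strides$cadence <- 120 / strides$duration
  strides
}

#' Step-level metrics
#'
#' Step length and step time are already carried by the step table built in
#' segmentation; this accessor renames them to the reporting vocabulary.
#'
#' @param steps Step data frame from [build_strides_and_steps()].
#' @return Data frame with `side`, `t_start`, `t_end`, `step_length` (m) and
#'   `step_time` (s).
#' @export
step_metrics <- function(steps) {
  data.frame(side = steps$side, t_start = steps$t_start, t_end = steps$t_end,
             step_length = steps$length, step_time = steps$duration,
             stringsAsFactors = FALSE)
}

#' Double support and foot off within one gait cycle
#'
#' Double support is the total time inside the cycle `[t_start, t_end)` where
#' both ankle labels are stance (0); foot off is the stance time of the
#' stride's own side within the cycle, as a percentage of the cycle duration.
#'
#' @param left,right `phase_label_series` for the two ankles on a shared
#'   grid covering the stride span.
#' @param stride One-row stride data frame (or list) with `side`, `t_start`,
#'   `t_end`.
#' @return List with `double_support` (s) and `foot_off_pct` (%).
#' @export
cycle_timing <- function(left, right, stride) {
  times <- left$times
  if (length(times) != length(right$times) ||
      max(abs(times - right$times)) > 1e-9)
    stop("label series do not share a time grid", call. = FALSE)
  if (stride$t_start < times[1L] - 1e-9 ||
      stride$t_end > times[length(times)] + 1e-9)
    stop("labels do not cover the stride span", call. = FALSE)
  dt <- stats::median(diff(times))
  in_cycle <- times >= stride$t_start - 1e-9 & times < stride$t_end - 1e-9
  both_stance <- left$labels == 0L & right$labels == 0L
  ds <- sum(both_stance & in_cycle) * dt
  own <- if (stride$side == "left") left else right
  stance_own <- sum(own$labels == 0L & in_cycle) * dt
  list(double_support = ds,
       foot_off_pct = 100 * stance_own / (stride$t_end - stride$t_start))
}

#' Assemble per-stride gait parameter records
#'
#' One record per detected stride carrying the eight reported parameters:
#' step length/time (from the step terminating at the stride's closing
#' contact, `NA` when that step was not detected or was gated out), stride
#' length/time, double support, foot off, walking speed and cadence.
#'
#' @param strides,steps Tables from [build_strides_and_steps()].
#' @param left,right `phase_label_series` used for cycle timing.
#' @param trial_id Trial identifier stamped on each record.
#' @return Data frame with columns `trial_id`, `side`, `t_start`, `t_end`,
#'   `step_length`, `step_time`, `stride_length`, `stride_time`,
#'   `double_support`, `foot_off_pct`, `walking_speed`, `cadence`.
#' @export
gait_parameter_records <- function(strides, steps, left, right,
                                   trial_id = "trial") {
  strides <- stride_metrics(strides)
  steps <- step_metrics(steps)
  n <- nrow(strides)
  rec <- data.frame(trial_id = rep(trial_id, n), side = strides$side,
                    t_start = strides$t_start, t_end = strides$t_end,
                    step_length = rep(NA_real_, n), step_time = rep(NA_real_, n),
                    stride_length = strides$length,
                    stride_time = strides$duration,
                    double_support = rep(NA_real_, n),
                    foot_off_pct = rep(NA_real_, n),
                    walking_speed = strides$walking_speed,
                    cadence = strides$cadence, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    tim <- cycle_timing(left, right, strides[i, ])
    rec$double_support[i] <- tim$double_support
    rec$foot_off_pct[i] <- tim$foot_off_pct
    j <- which(steps$side == strides$side[i] &
                 abs(steps$t_end - strides$t_end[i]) < 1e-9)
    if (length(j) == 1L) {
      rec$step_length[i] <- steps$step_length[j]
      rec$step_time[i] <- steps$step_time[j]
    }
  }
  rec
}

PARAMETER_NAMES <- c("step_length", "step_time", "stride_length", "stride_time",
                     "double_support", "foot_off_pct", "walking_speed",
                     "cadence")

#' Pool gait parameter records into a summary table
#'
#' Parameters are computed per stride for each leg and then pooled. With
#' `pooling = "trial_mean"` (default) records are first averaged within each
#' trial (both sides together) and the summary is taken across trial means,
#' matching a per-trial analysis of a few consistent trials per subject; with
#' `pooling = "stride"` every stride-level record enters the pool directly.
#' Dispersion is the sample standard deviation (n - 1).
#'
#' @param records Record table from [gait_parameter_records()] (rows from
#'   several trials may be concatenated).
#' @param pooling `"trial_mean"` or `"stride"`.
#' @return Data frame with one row per parameter: `parameter`, `mean`, `sd`,
#'   `n` (number of pooled observations; `sd` is `NA` when `n < 2`).
#' @export
aggregate_parameters <- function(records, pooling = c("trial_mean", "stride")) {
  pooling <- match.arg(pooling)
  if (!nrow(records)) stop("no records to aggregate", call. = FALSE)
  pool <- if (pooling == "trial_mean") {
    do.call(rbind, lapply(split(records, records$trial_id), function(d) {
      as.data.frame(lapply(d[PARAMETER_NAMES], mean, na.rm = TRUE))
    }))
  } else records[PARAMETER_NAMES]
  out <- data.frame(parameter = PARAMETER_NAMES,
                    mean = NA_real_, sd = NA_real_, n = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(PARAMETER_NAMES)) {
    v <- pool[[PARAMETER_NAMES[i]]]
    v <- v[is.finite(v)]
    out$mean[i] <- mean(v)
    out$sd[i] <- if (length(v) >= 2L) stats::sd(v) else NA_real_
    out$n[i] <- length(v)
  }
  out
}
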