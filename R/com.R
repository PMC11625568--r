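#' Center-of-mass proxy from the hip joints
#'
#' The camera-side CoM proxy: the midpoint between the left and right 3D hip
#' joints of the skeletal model, frame by frame.
#'
#' @param traj A [skeleton_trajectory_set] containing `HIP_LEFT` and
#'   `HIP_RIGHT`.
#' @return An object of class `com_trajectory`: list with `times`, `position`
#'   (`n x 3` matrix, meters), `axis_roles` and `source = "hips_midpoint"`.
#' @export
com_from_hips <- function(traj) {
  for (j in c("HIP_LEFT", "HIP_RIGHT"))
    if (!j %in% names(traj$joints))
      stop("missing hip joint ", j, call. = FALSE)
  pos <- (traj$joints[["HIP_LEFT"]] + traj$joints[["HIP_RIGHT"]]) / 2
  structure(list(times = traj$times, position = pos,
                 axis_roles = traj$axis_roles, source = "hips_midpoint"),
            class = "com_trajectory")
}

#' Center-of-mass proxy from the four pelvis markers
#'
#' The reference-system construction: the midpoint of the segment joining the
#' midpoint of the two anterior superior iliac spine markers and the midpoint
#' of the two posterior ones.
#'
#' @param markers A [marker_trajectory_set] with LASI/RASI/LPSI/RPSI.
#' @return A `com_trajectory` with `source = "pelvis_markers"`.
#' @export
com_from_pelvis_markers <- function(markers) {
  m <- markers$markers
  asis <- (m$LASI + m$RASI) / 2
  psis <- (m$LPSI + m$RPSI) / 2
  structure(list(times = markers$times, position = (asis + psis) / 2,
                 axis_roles = markers$axis_roles, source = "pelvis_markers"),
            class = "com_trajectory")
}

#' @export
print.com_trajectory <- function(x, ...) {
  cat("CoM trajectory (", x$source, "): ", length(x$times), " samples over ",
      sprintf("%.2f", diff(range(x$times))), " s\n", sep = "")
  invisible(x)
}

#' Per-cycle CoM excursions along ML, V and AP
#'
#' For each gait cycle (stride span `[t_start, t_end)`), the maximum excursion
#' of the CoM along each body-frame direction, taken as peak-to-peak (max
#' minus min) of the role-mapped coordinate within the cycle and reported in
#' millimeters. Along AP this is the progression of the body over the cycle
#' (approximately the stride length), not a sway. Cycles from both sides
#' contribute to the pool. An optional linear detrend of ML and V supports
#' walks not aligned with a coordinate axis; the laboratory setup emulated
#' here is axis-aligned, so the default is off.
#'
#' @param com A `com_trajectory`.
#' @param strides Stride table from [build_strides_and_steps()].
#' @param detrend_ml_v Remove a linear trend from ML and V within each cycle
#'   before taking max - min (default `FALSE`).
#' @param mode `"ptp"` (peak-to-peak, default) or `"from_mean"` (largest
#'   absolute deviation from the cycle mean).
#' @return Data frame with `cycle_id`, `side`, `t_start`, `t_end`, `ap_mm`,
#'   `ml_mm`, `v_mm`. Cycles outside the trajectory span are skipped with a
#'   warning.
#' @export
excursions_per_cycle <- function(com, strides, detrend_ml_v = FALSE,
                                 mode = c("ptp", "from_mean")) {
  mode <- match.arg(mode)
  out <- data.frame(cycle_id = integer(), side = character(),
                    t_start = numeric(), t_end = numeric(),
                    ap_mm = numeric(), ml_mm = numeric(), v_mm = numeric(),
                    stringsAsFactors = FALSE)
  if (!nrow(strides)) return(out)
  exc <- function(v) {
    if (mode == "ptp") max(v) - min(v) else max(abs(v - mean(v)))
  }
  cols <- vapply(c("ap", "ml", "v"), function(r) axis_col(com$axis_roles, r),
                 integer(1))
  for (i in seq_len(nrow(strides))) {
    # closed window: the closing contact instant belongs to the cycle, so the
    # AP excursion of a complete cycle equals the full cycle progression
    idx <- which(com$times >= strides$t_start[i] - 1e-9 &
                   com$times <= strides$t_end[i] + 1e-9)
    if (length(idx) < 2L ||
        strides$t_start[i] < com$times[1L] - 1e-9 ||
        strides$t_end[i] > com$times[length(com$times)] + 0.05) {
      warning("cycle ", i, " outside CoM trajectory span: skipped")
      next
    }
    seg <- com$position[idx, , drop = FALSE]
    vals <- numeric(3)
    for (k in 1:3) {
      v <- seg[, cols[k]]
      if (detrend_ml_v && k > 1L)
        v <- stats::residuals(stats::lm(v ~ com$times[idx]))
      vals[k] <- exc(v)
    }
    out <- rbind(out, data.frame(cycle_id = i, side = strides$side[i],
                                 t_start = strides$t_start[i],
                                 t_end = strides$t_end[i],
                                 ap_mm = vals[1] * 1000,
                                 ml_mm = vals[2] * 1000,
                                 v_mm = vals[3] * 1000,
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Pool per-cycle CoM excursions
#'
#' @param excursions Table from [excursions_per_cycle()].
#' @return Data frame with one row per direction (`ap_mm`, `ml_mm`, `v_mm`):
#'   mean, sample SD and n over all pooled cycles.
#' @export
aggregate_excursions <- function(excursions) {
  dirs <- c("ap_mm", "ml_mm", "v_mm")
  data.frame(direction = c("AP", "ML", "V"),
             mean = vapply(dirs, function(d) mean(excursions[[d]]), numeric(1)),
             sd = vapply(dirs, function(d)
               if (nrow(excursions) >= 2L) stats::sd(excursions[[d]]) else NA_real_,
               numeric(1)),
             n = nrow(excursions), stringsAsFactors = FALSE, row.names = NULL)
}
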