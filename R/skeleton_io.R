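#' Joint names required by the analysis pipeline
#'
#' The body-tracking vocabulary has 32 joints; segmentation needs both ankles
#' and the CoM proxy needs both hips. Any further joints are carried through
#' untouched.
#' @keywords internal
REQUIRED_JOINTS <- c("ANKLE_LEFT", "ANKLE_RIGHT", "HIP_LEFT", "HIP_RIGHT")

#' Construct a skeletal trajectory set
#'
#' The in-memory container for one walking trial: a shared strictly-increasing
#' timestamp vector plus, per joint, an `n x 3` position matrix in meters with
#' columns `x`, `y`, `z`. Timestamps are re-based so the first frame is at 0 s
#' (device clocks are arbitrary).
#'
#' @param trial_id Character trial identifier.
#' @param times Numeric vector of frame timestamps in seconds, strictly
#'   increasing.
#' @param joints Named list of `length(times) x 3` numeric matrices (meters).
#' @param system `"MAK"` or `"MoCap"`; sets the axis-role convention.
#' @param fps_nominal Nominal frame rate in Hz (e.g. 30).
#' @param rebase Re-base timestamps to start at 0 (default `TRUE`).
#' @return An object of class `skeleton_trajectory_set`.
#' @export
skeleton_trajectory_set <- function(trial_id, times, joints, system = "MAK",
                                    fps_nominal = 30, rebase = TRUE) {
  times <- as.numeric(times)
  if (anyNA(times) || any(!is.finite(times)))
    stop("timestamps must be finite", call. = FALSE)
  bad <- which(diff(times) <= 0)
  if (length(bad))
    stop("timestamps not strictly increasing at indices ",
         paste(utils::head(bad + 1L, 10L), collapse = ", "), call. = FALSE)
  if (!length(joints) || is.null(names(joints)) || any(names(joints) == ""))
    stop("joints must be a non-empty named list", call. = FALSE)
  joints <- lapply(joints, function(m) {
    m <- as.matrix(m)
    if (nrow(m) != length(times) || ncol(m) != 3L)
      stop("each joint needs one x,y,z row per timestamp", call. = FALSE)
    storage.mode(m) <- "double"
    colnames(m) <- c("x", "y", "z")
    m
  })
  if (rebase) times <- times - times[1L]
  structure(list(trial_id = as.character(trial_id), system = system,
                 fps_nominal = fps_nominal, times = times, joints = joints,
                 axis_roles = axis_roles_for(system),
                 load_report = list(frames_dropped = 0L, frames_total = length(times))),
            class = "skeleton_trajectory_set")
}

#' @export
print.skeleton_trajectory_set <- function(x, ...) {
  cat("skeleton trajectory set '", x$trial_id, "' (", x$system, ")\n", sep = "")
  cat("  ", length(x$times), " frames over ",
      sprintf("%.2f", diff(range(x$times))), " s (nominal ",
      x$fps_nominal, " fps)\n", sep = "")
  cat("  joints:", paste(names(x$joints), collapse = ", "), "\n")
  if (x$load_report$frames_dropped > 0L)
    cat("  dropped", x$load_report$frames_dropped, "frames on load\n")
  invisible(x)
}

#' Read an RGB-D body-tracking stream from JSON
#'
#' Reads the documented stream schema
#' `{"trial_id", "fps_nominal", "units": "mm"|"m",
#'   "frames": [{"t": sec, "joints": {"ANKLE_LEFT": [x,y,z], ...}}]}`
#' and returns a validated [skeleton_trajectory_set] in meters with the camera
#' axis roles (ML = x, V = y, AP = depth = z). Frames in which any required
#' joint (ankles, hips) is absent or non-finite are dropped and counted in the
#' load report; the later resampling stage bridges the gaps.
#'
#' @param path Path to the JSON file.
#' @param units Override for the position units if the file omits the `units`
#'   field; `"m"` or `"mm"`.
#' @return A `skeleton_trajectory_set`; its `load_report` records
#'   `frames_dropped` and `frames_total`.
#' @seealso [write_mak_json()]
#' @export
read_mak_json <- function(path, units = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("malformed JSON in '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (is.null(doc$frames) || !length(doc$frames))
    stop("stream '", path, "' has no frames", call. = FALSE)
  units <- if (!is.null(doc$units)) doc$units else if (!is.null(units)) units else "m"
  if (!units %in% c("m", "mm")) stop("units must be 'm' or 'mm'", call. = FALSE)
  scale <- if (units == "mm") 1e-3 else 1

  times <- vapply(doc$frames, function(f) as.numeric(f$t), numeric(1))
  bad <- which(diff(times) <= 0)
  if (length(bad))
    stop("non-monotone timestamps in '", path, "' at frame indices ",
         paste(utils::head(bad + 1L, 10L), collapse = ", "), call. = FALSE)

  joint_names <- unique(unlist(lapply(doc$frames, function(f) names(f$joints))))
  frame_ok <- vapply(doc$frames, function(f) {
    all(vapply(REQUIRED_JOINTS, function(j) {
      p <- f$joints[[j]]
      !is.null(p) && length(p) == 3L && all(is.finite(unlist(p)))
    }, logical(1)))
  }, logical(1))
  n_total <- length(doc$frames)
  n_drop <- sum(!frame_ok)
  if (n_drop > n_total / 2)
    stop("required joints (", paste(REQUIRED_JOINTS, collapse = ", "),
         ") absent in ", n_drop, "/", n_total, " frames of '", path, "'",
         call. = FALSE)
  frames <- doc$frames[frame_ok]
  times <- times[frame_ok]

  joints <- lapply(joint_names, function(j) {
    m <- t(vapply(frames, function(f) {
      p <- f$joints[[j]]
      if (is.null(p) || length(p) != 3L) rep(NA_real_, 3L) else as.numeric(unlist(p))
    }, numeric(3)))
    m * scale
  })
  names(joints) <- joint_names

  out <- skeleton_trajectory_set(
    trial_id = if (!is.null(doc$trial_id)) doc$trial_id else basename(path),
    times = times, joints = joints, system = "MAK",
    fps_nominal = if (!is.null(doc$fps_nominal)) doc$fps_nominal else 30)
  out$load_report <- list(frames_dropped = n_drop, frames_total = n_total)
  out
}

#' Write a skeletal trajectory set to the JSON stream schema
#'
#' @param traj A [skeleton_trajectory_set].
#' @param path Output path.
#' @param units `"m"` (default) or `"mm"` for the serialized positions.
#' @return `path`, invisibly.
#' @export
write_mak_json <- function(traj, path, units = c("m", "mm")) {
  units <- match.arg(units)
  scale <- if (units == "mm") 1e3 else 1
  frames <- lapply(seq_along(traj$times), function(i) {
    js <- lapply(traj$joints, function(m) unname(m[i, ] * scale))
    list(t = traj$times[i], joints = js)
  })
  doc <- list(trial_id = traj$trial_id, fps_nominal = traj$fps_nominal,
              units = units, frames = frames)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

PELVIS_MARKERS <- c("LASI", "RASI", "LPSI", "RPSI")

#' Construct a pelvis marker trajectory set
#'
#' Carrier for the four-marker pelvis set (left/right anterior and posterior
#' superior iliac spines) used by the marker-based CoM construction.
#'
#' @param times Timestamps in seconds, strictly increasing.
#' @param markers Named list with elements `LASI`, `RASI`, `LPSI`, `RPSI`,
#'   each an `n x 3` matrix in meters.
#' @param rate Sampling rate in Hz (e.g. 100).
#' @return An object of class `marker_trajectory_set`.
#' @export
marker_trajectory_set <- function(times, markers, rate = 100) {
  missing <- setdiff(PELVIS_MARKERS, names(markers))
  if (length(missing))
    stop("missing marker ", paste(missing, collapse = ", "), call. = FALSE)
  times <- as.numeric(times)
  if (any(diff(times) <= 0))
    stop("marker timestamps not strictly increasing", call. = FALSE)
  markers <- lapply(markers[PELVIS_MARKERS], function(m) {
    m <- as.matrix(m)
    if (nrow(m) != length(times) || ncol(m) != 3L)
      stop("each marker needs one x,y,z row per timestamp", call. = FALSE)
    storage.mode(m) <- "double"
    colnames(m) <- c("x", "y", "z")
    m
  })
  structure(list(times = times, markers = markers, rate = rate,
                 axis_roles = axis_roles_for("MoCap")),
            class = "marker_trajectory_set")
}

#' Read pelvis marker trajectories from CSV
#'
#' Expects a header `time,LASI_x,LASI_y,LASI_z,RASI_x,...` with one row per
#' frame and all four pelvis markers present; positions in meters.
#'
#' @param path CSV path.
#' @param rate Sampling rate in Hz recorded on the returned set.
#' @return A [marker_trajectory_set].
#' @export
read_marker_csv <- function(path, rate = 100) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  nf <- utils::count.fields(path, sep = ",")
  if (length(unique(nf)) > 1L)
    stop("ragged CSV '", path, "': line ",
         which(nf != nf[1L])[1L], " has ", nf[nf != nf[1L]][1L],
         " fields, expected ", nf[1L], call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df)) stop("missing 'time' column", call. = FALSE)
  markers <- lapply(PELVIS_MARKERS, function(m) {
    cols <- paste0(m, "_", c("x", "y", "z"))
    if (!all(cols %in% names(df)))
      stop("missing marker ", m, call. = FALSE)
    as.matrix(df[, cols])
  })
  names(markers) <- PELVIS_MARKERS
  marker_trajectory_set(df$time, markers, rate = rate)
}

#' Write pelvis marker trajectories to CSV
#'
#' @param markers A [marker_trajectory_set].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_marker_csv <- function(markers, path) {
  df <- data.frame(time = markers$times)
  for (m in PELVIS_MARKERS) {
    cols <- paste0(m, "_", c("x", "y", "z"))
    pos <- markers$markers[[m]]
    for (k in 1:3) df[[cols[k]]] <- pos[, k]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Shared grid accessor: one joint's single-axis series.
joint_axis_series <- function(traj, joint, role) {
  if (!joint %in% names(traj$joints))
    stop("joint ", joint, " not present in trial '", traj$trial_id, "'",
         call. = FALSE)
  traj$joints[[joint]][, axis_col(traj$axis_roles, role)]
}
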