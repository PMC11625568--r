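#' Segmentation configuration
#'
#' Parameters of the stance/swing threshold rule and of the virtual
#' gait-analysis path (VGAP) gate. An ankle sample is labeled swing when its
#' depth moved more than `threshold` since the previous sample; at the 50 Hz
#' analysis rate the default 0.02 m threshold is a 1 m/s velocity gate.
#' Strides and steps are retained only when both bounding events lie inside
#' the `[vgap_near, vgap_far]` depth window (the camera loses whole-body
#' framing nearer than ~1.5 m and tracking reliability beyond ~4.5 m).
#'
#' @param threshold Depth-delta threshold in meters between consecutive
#'   samples. Default 0.02.
#' @param min_phase_samples Debounce: phase runs shorter than this many
#'   samples are merged into the surrounding phase. Default 3 (60 ms at
#'   50 Hz).
#' @param vgap_near,vgap_far Near and far bounds (m) of the accepted depth
#'   window. Defaults 1.5 and 4.5.
#' @param step_variant `"contralateral"` (conventional step: opposite foot
#'   contact to this foot's next contact) or `"single_ankle"` (one ankle's
#'   swing displacement).
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(threshold = 0.02, min_phase_samples = 3,
                                vgap_near = 1.5, vgap_far = 4.5,
                                step_variant = c("contralateral", "single_ankle")) {
  stopifnot(threshold > 0, min_phase_samples >= 1)
  if (vgap_near >= vgap_far) stop("vgap_near must be < vgap_far", call. = FALSE)
  structure(list(threshold = threshold,
                 min_phase_samples = as.integer(min_phase_samples),
                 vgap_near = vgap_near, vgap_far = vgap_far,
                 step_variant = match.arg(step_variant)),
            class = "segmentation_config")
}

# Merge label runs shorter than min_len into their surroundings.  Flipping the
# currently shortest offending run and re-running rle() until stable is O(n
# runs) and order-independent enough for debouncing chatter near the gate.
debounce_labels <- function(labels, min_len) {
  if (min_len <= 1L) return(labels)
  repeat {
    r <- rle(labels)
    if (length(r$lengths) == 1L) return(labels)
    short <- which(r$lengths < min_len)
    if (!length(short)) return(labels)
    i <- short[which.min(r$lengths[short])]
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    labels[starts[i]:ends[i]] <- 1L - r$values[i]
  }
}

#' Label ankle samples stance (0) or swing (1)
#'
#' Implements the depth-delta rule: sample `i` is swing iff
#' `|depth[i] - depth[i-1]| > threshold`, stance otherwise (a tie at exactly
#' the threshold counts as stance: motion requires strictly greater). The
#' first sample copies the second. With `debounce = TRUE`, runs shorter than
#' `min_phase_samples` are merged into the surrounding phase.
#'
#' @param depth Ankle depth series in meters (uniformly resampled and
#'   filtered), length >= 2.
#' @param times Timestamps matching `depth`.
#' @param side `"left"` or `"right"`.
#' @param config A [segmentation_config].
#' @param debounce Apply the minimum-phase-length debounce (default `TRUE`).
#' @return An object of class `phase_label_series`: list with `side`,
#'   `times`, `depth`, `labels` (post-debounce) and `raw_labels`
#'   (pre-debounce).
#' @export
label_phases <- function(depth, times, side = c("left", "right"),
                         config = segmentation_config(), debounce = TRUE) {
  side <- match.arg(side)
  n <- length(depth)
  if (n < 2L) stop("need at least 2 samples to label phases", call. = FALSE)
  if (length(times) != n) stop("times and depth lengths differ", call. = FALSE)
  raw <- integer(n)
  raw[2:n] <- as.integer(abs(diff(depth)) > config$threshold)
  raw[1L] <- raw[2L]
  labels <- if (debounce) debounce_labels(raw, config$min_phase_samples) else raw
  structure(list(side = side, times = times, depth = depth,
                 labels = labels, raw_labels = raw),
            class = "phase_label_series")
}

#' @export
print.phase_label_series <- function(x, ...) {
  r <- rle(x$labels)
  cat("phase labels (", x$side, "): ", length(x$labels), " samples, ",
      sum(r$values == 0L), " stance / ", sum(r$values == 1L),
      " swing phases\n", sep = "")
  invisible(x)
}

#' Extract gait events from phase labels
#'
#' Each swing-to-stance transition emits a `stance_onset` (initial contact)
#' and each stance-to-swing transition a `swing_onset` (foot off), at the
#' first sample of the new phase, with the ankle depth at that sample.
#' Alternation per side holds by construction.
#'
#' @param left,right `phase_label_series` for the two ankles, sharing one
#'   time grid. Either may be `NULL` to extract one side only.
#' @return A data frame with columns `side`, `kind`, `index`, `time`,
#'   `depth`, sorted by time. Sides with no transitions contribute no rows
#'   (with a warning).
#' @export
extract_events <- function(left = NULL, right = NULL) {
  one <- function(s) {
    if (is.null(s)) return(NULL)
    l <- s$labels
    tr <- which(diff(l) != 0L) + 1L
    if (!length(tr)) {
      warning("no phase transitions on ", s$side, " side")
      return(NULL)
    }
    data.frame(side = s$side,
               kind = ifelse(l[tr] == 0L, "stance_onset", "swing_onset"),
               index = tr, time = s$times[tr], depth = s$depth[tr],
               stringsAsFactors = FALSE)
  }
  ev <- rbind(one(left), one(right))
  if (is.null(ev))
    return(data.frame(side = character(), kind = character(),
                      index = integer(), time = numeric(), depth = numeric(),
                      stringsAsFactors = FALSE))
  ev <- ev[order(ev$time, ev$side), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Build strides and steps from gait events
#'
#' A stride is the interval between two consecutive stance onsets of the same
#' foot; its length is the absolute depth difference between them (the
#' subject walks toward the camera, so depth decreases). A step
#' (`"contralateral"` variant, conventional) runs from the opposite foot's
#' stance onset to this foot's next stance onset; its length is the absolute
#' difference between the two ankles' depths at their respective onsets. The
#' `"single_ankle"` variant instead takes one ankle's swing (swing onset to
#' next stance onset of the same side), the literal one-foot reading, whose
#' displacement is a full stride length. Strides and steps are kept only when
#' both bounding events lie inside the VGAP depth window.
#'
#' @param events Event data frame from [extract_events()].
#' @param config A [segmentation_config].
#' @param gate_vgap Apply the VGAP depth gate (default `TRUE`).
#' @return List with data frames `strides` (`side`, `t_start`, `t_end`,
#'   `depth_start`, `depth_end`, `length`, `duration`) and `steps` (same
#'   columns; `side` is the side of the terminating contact).
#' @export
build_strides_and_steps <- function(events, config = segmentation_config(),
                                    gate_vgap = TRUE) {
  in_vgap <- function(d) d >= config$vgap_near & d <= config$vgap_far
  empty <- data.frame(side = character(), t_start = numeric(),
                      t_end = numeric(), depth_start = numeric(),
                      depth_end = numeric(), length = numeric(),
                      duration = numeric(), stringsAsFactors = FALSE)
  span <- function(side, t1, t2, d1, d2) {
    data.frame(side = side, t_start = t1, t_end = t2,
               depth_start = d1, depth_end = d2,
               length = abs(d2 - d1), duration = t2 - t1,
               stringsAsFactors = FALSE)
  }

  strides <- empty
  for (s in c("left", "right")) {
    on <- events[events$side == s & events$kind == "stance_onset", , drop = FALSE]
    if (nrow(on) < 2L) {
      if (nrow(events[events$side == s, , drop = FALSE]))
        warning("fewer than 2 stance onsets on ", s, " side: no strides")
      next
    }
    i <- seq_len(nrow(on) - 1L)
    strides <- rbind(strides, span(s, on$time[i], on$time[i + 1L],
                                   on$depth[i], on$depth[i + 1L]))
  }

  steps <- empty
  if (config$step_variant == "contralateral") {
    on <- events[events$kind == "stance_onset", , drop = FALSE]
    on <- on[order(on$time), , drop = FALSE]
    if (nrow(on) >= 2L) {
      for (i in 2:nrow(on)) {
        if (on$side[i] == on$side[i - 1L]) next  # missed contralateral contact
        steps <- rbind(steps, span(on$side[i], on$time[i - 1L], on$time[i],
                                   on$depth[i - 1L], on$depth[i]))
      }
    }
  } else {
    for (s in c("left", "right")) {
      ev <- events[events$side == s, , drop = FALSE]
      off <- which(ev$kind == "swing_onset")
      off <- off[off < nrow(ev)]
      for (i in off)
        steps <- rbind(steps, span(s, ev$time[i], ev$time[i + 1L],
                                   ev$depth[i], ev$depth[i + 1L]))
    }
  }

  if (gate_vgap) {
    keep_st <- in_vgap(strides$depth_start) & in_vgap(strides$depth_end)
    strides <- strides[keep_st, , drop = FALSE]
    keep_sp <- in_vgap(steps$depth_start) & in_vgap(steps$depth_end)
    steps <- steps[keep_sp, , drop = FALSE]
  }
  rownames(strides) <- rownames(steps) <- NULL
  list(strides = strides, steps = steps)
}
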