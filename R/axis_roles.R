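#' Axis-role conventions for a tracking system
#'
#' Downstream code never addresses raw `x`/`y`/`z` coordinates; it asks for the
#' antero-posterior (AP, walking direction), medio-lateral (ML) and vertical (V)
#' role of each axis. The two supported coordinate systems differ: the depth
#' camera (MAK) encodes the walking direction on its depth axis `z` with ML on
#' `x`, whereas the laboratory motion-capture frame has the walkway along `x`
#' and ML on `z`. Both systems carry the vertical on `y`.
#'
#' @param system `"MAK"` (RGB-D camera frame) or `"MoCap"` (laboratory frame).
#' @return An object of class `axis_roles`: a list with elements `ap_axis`,
#'   `ml_axis`, `v_axis` (each one of `"x"`, `"y"`, `"z"`, mutually distinct)
#'   and `depth_axis` (the axis encoding distance from the camera, `NA` for
#'   systems without a depth sensor).
#' @examples
#' axis_roles_for("MAK")$ml_axis    # "x"
#' axis_roles_for("MoCap")$ap_axis  # "x"
#' @export
axis_roles_for <- function(system) {
  if (length(system) != 1L || !system %in% c("MAK", "MoCap"))
    stop("unknown system '", paste(system, collapse = ","),
         "'; expected \"MAK\" or \"MoCap\"", call. = FALSE)
  if (system == "MAK")
    axis_roles(ap = "z", ml = "x", v = "y", depth = "z")
  else
    axis_roles(ap = "x", ml = "z", v = "y", depth = NA_character_)
}

#' Construct an axis-role map
#'
#' @param ap,ml,v Axis names (`"x"`, `"y"` or `"z"`) carrying the
#'   antero-posterior, medio-lateral and vertical roles; must be a permutation
#'   of the three axes.
#' @param depth Axis encoding distance from the sensor, or `NA`.
#' @return An `axis_roles` object.
#' @export
axis_roles <- function(ap, ml, v, depth = NA_character_) {
  roles <- c(ap = ap, ml = ml, v = v)
  if (!setequal(roles, c("x", "y", "z")))
    stop("ap/ml/v must be a permutation of x, y, z; got ",
         paste(roles, collapse = ","), call. = FALSE)
  if (!is.na(depth) && !depth %in% c("x", "y", "z"))
    stop("depth axis must be x, y, z or NA", call. = FALSE)
  structure(list(ap_axis = unname(ap), ml_axis = unname(ml),
                 v_axis = unname(v), depth_axis = unname(depth)),
            class = "axis_roles")
}

#' @export
print.axis_roles <- function(x, ...) {
  cat("axis roles: AP =", x$ap_axis, "| ML =", x$ml_axis,
      "| V =", x$v_axis, "| depth =", x$depth_axis, "\n")
  invisible(x)
}

# Column index (1..3) of a role in an n x 3 position matrix ordered x,y,z.
axis_col <- function(roles, role = c("ap", "ml", "v", "depth")) {
  role <- match.arg(role)
  ax <- switch(role, ap = roles$ap_axis, ml = roles$ml_axis,
               v = roles$v_axis, depth = roles$depth_axis)
  if (is.na(ax)) stop("system has no ", role, " axis", call. = FALSE)
  match(ax, c("x", "y", "z"))
}
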