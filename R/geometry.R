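# Calibrated 2-D geometry of a single radiographic view.
#
# Coordinate convention (all views): +x medial (toward the head apex).
# AP view: +y superior.  LAT view: +y anterior.  Left hips are mirrored in x
# at read time so "medial" is always +x.

#' Construct landmark annotations for one radiographic view
#'
#' Bundles the annotated geometry of one view (AP or LAT) of a hip
#' radiograph: the femoral head modelled as a circle, the femoral neck
#' central axis, the lag-screw tip and axis, the measured screw diameter
#' used for calibration, and (AP only) a point on the medial calcar cortex.
#' All coordinates are in arbitrary image units; calibration to millimetres
#' uses the known true screw diameter.
#'
#' @param view_label `"AP"` or `"LAT"`.
#' @param head_center Numeric length-2, centre of the femoral head circle.
#' @param head_radius Positive head-circle radius (image units).
#' @param neck_axis_point A point on the femoral neck central axis.
#' @param neck_axis_dir Direction of the neck axis, pointing medially
#'   (toward the head apex); normalised on construction.
#' @param screw_tip Lag-screw tip (point A).
#' @param screw_axis_dir Direction along the lag screw, pointing medially;
#'   normalised on construction.
#' @param screw_diameter_measured Measured lag-screw diameter in image units.
#' @param calcar_point Optional point on the medial calcar cortex (AP only);
#'   required for the calcar-referenced TAD.
#' @return An object of class `view_landmarks`.
#' @export
view_landmarks <- function(view_label, head_center, head_radius,
                           neck_axis_point, neck_axis_dir,
                           screw_tip, screw_axis_dir,
                           screw_diameter_measured,
                           calcar_point = NULL) {
  view_label <- match.arg(view_label, c("AP", "LAT"))
  stopifnot(length(head_center) == 2L, length(neck_axis_point) == 2L,
            length(screw_tip) == 2L)
  if (!is.finite(head_radius) || head_radius <= 0)
    stop_mtad("invalid_landmark", "head_radius must be positive")
  if (!is.finite(screw_diameter_measured) || screw_diameter_measured <= 0)
    stop_mtad("invalid_landmark", "screw_diameter_measured must be positive")
  structure(list(
    view_label = view_label,
    head_center = as.numeric(head_center),
    head_radius = as.numeric(head_radius),
    neck_axis_point = as.numeric(neck_axis_point),
    neck_axis_dir = unit2(neck_axis_dir),
    screw_tip = as.numeric(screw_tip),
    screw_axis_dir = unit2(screw_axis_dir),
    screw_diameter_measured = as.numeric(screw_diameter_measured),
    calcar_point = if (is.null(calcar_point)) NULL else as.numeric(calcar_point)
  ), class = "view_landmarks")
}

#' @export
print.view_landmarks <- function(x, ...) {
  cat(sprintf("<view_landmarks %s> head c=(%.4g, %.4g) r=%.4g; tip=(%.4g, %.4g)\n",
              x$view_label, x$head_center[1], x$head_center[2], x$head_radius,
              x$screw_tip[1], x$screw_tip[2]))
  invisible(x)
}

# normalise to a unit 2-vector; zero vector is a landmark error
unit2 <- function(v) {
  v <- as.numeric(v)
  stopifnot(length(v) == 2L)
  n <- sqrt(sum(v^2))
  if (!is.finite(n) || n < 1e-12)
    stop_mtad("invalid_landmark", "degenerate (zero) direction vector")
  v / n
}

# 90-degree counter-clockwise rotation
perp2 <- function(v) c(-v[2], v[1])

#' Pixel-to-millimetre calibration for one view
#'
#' Each view is calibrated independently (AP and LAT magnifications differ)
#' using the lag-screw diameter visible in that view as the in-image
#' reference; the true diameter defaults to 12.5 mm, the standard DHS lag
#' screw.
#'
#' @param lm A [view_landmarks()] object.
#' @param true_diameter_mm True lag-screw diameter in mm (default 12.5).
#' @return A list with `scale` (mm per image unit) and `true_diameter_mm`.
#' @export
calibration_for_view <- function(lm, true_diameter_mm = 12.5) {
  if (!is.finite(true_diameter_mm) || true_diameter_mm <= 0)
    stop_mtad("invalid_landmark", "true_diameter_mm must be positive")
  if (!is.finite(lm$screw_diameter_measured) || lm$screw_diameter_measured <= 0)
    stop_mtad("invalid_landmark", "measured screw diameter must be positive")
  list(scale = true_diameter_mm / lm$screw_diameter_measured,
       true_diameter_mm = true_diameter_mm)
}

#' Far intersection of a line with a circle
#'
#' Solves \eqn{|o + t d - c| = r} for the parameter \eqn{t} and returns the
#' intersection at the larger \eqn{t} along `dir` -- the far (medial-side)
#' surface point.  `t` may be negative when `origin` already lies beyond the
#' far surface; callers flag that case (screw penetration) rather than error.
#'
#' @param origin,dir Line origin and unit direction.
#' @param center,radius Circle centre and radius.
#' @return A list with `point` (length-2) and the parameter `t`.
#' @export
line_circle_far_intersection <- function(origin, dir, center, radius) {
  dir <- unit2(dir)
  oc <- as.numeric(origin) - as.numeric(center)
  b <- sum(dir * oc)
  cc <- sum(oc^2) - radius^2
  disc <- b^2 - cc
  if (disc < 0)
    stop_mtad("no_intersection", "line does not intersect the circle")
  t <- -b + sqrt(disc)
  list(point = as.numeric(origin) + t * dir, t = t)
}

#' Femoral head apex
#'
#' The apex (point C) is defined as the intersection of the femoral neck
#' central axis with the head circle on the medial side (larger parameter
#' along the neck direction) -- the standard Baumgaertner construction, so
#' that a perfectly central screw has its far surface point at the apex.
#'
#' @param lm A [view_landmarks()] object.
#' @return Length-2 numeric apex point (image units).
#' @export
apex_point <- function(lm) {
  res <- tryCatch(
    line_circle_far_intersection(lm$neck_axis_point, lm$neck_axis_dir,
                                 lm$head_center, lm$head_radius),
    mtad_no_intersection = function(e)
      stop_mtad("invalid_landmark", "neck axis does not intersect the head circle")
  )
  res$point
}

#' Signed perpendicular offset of a point from an axis
#'
#' Projects `p - axis_point` onto the unit normal of `axis_dir` oriented
#' toward `positive_side` (superior in AP, anterior in LAT).  Positive when
#' `p` lies in the positive half-plane, negative on the other side, zero on
#' the axis.
#'
#' @param p Query point.
#' @param axis_point,axis_dir Axis through `axis_point` with unit direction.
#' @param positive_side Reference vector selecting the positive half-plane.
#' @return Signed perpendicular distance (same units as the coordinates).
#' @export
signed_offset_from_axis <- function(p, axis_point, axis_dir, positive_side) {
  axis_dir <- unit2(axis_dir)
  n <- perp2(axis_dir)
  if (sum(n * as.numeric(positive_side)) < 0) n <- -n
  sum((as.numeric(p) - as.numeric(axis_point)) * n)
}

# condition helpers ---------------------------------------------------------

stop_mtad <- function(kind, msg) {
  stop(structure(class = c(paste0("mtad_", kind), "mtad_error", "error",
                           "condition"),
                 list(message = msg, call = sys.call(-1))))
}
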