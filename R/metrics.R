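# The six lag-screw position parameters, computed from calibrated AP + LAT
# landmark geometry.  In the fixed coordinate convention the positive
# offset side is +y in both views (superior in AP, anterior in LAT).

POSITIVE_SIDE <- c(0, 1)

#' Pair the AP and LAT landmark sets of one case
#'
#' @param case_id Case identifier.
#' @param ap,lat [view_landmarks()] objects with matching `view_label`.
#' @param true_diameter_mm True lag-screw diameter used for calibration of
#'   both views (default 12.5 mm).
#' @return An object of class `case_radiographs`.
#' @export
case_radiographs <- function(case_id, ap, lat, true_diameter_mm = 12.5) {
  stopifnot(inherits(ap, "view_landmarks"), inherits(lat, "view_landmarks"))
  if (ap$view_label != "AP" || lat$view_label != "LAT")
    stop_mtad("invalid_landmark", "need exactly one AP and one LAT view")
  structure(list(case_id = case_id, ap = ap, lat = lat,
                 true_diameter_mm = true_diameter_mm),
            class = "case_radiographs")
}

# calibrated straight-line tip-to-apex distance for one view, in mm
tip_apex_term <- function(lm, true_diameter_mm) {
  cal <- calibration_for_view(lm, true_diameter_mm)
  apex <- apex_point(lm)
  cal$scale * sqrt(sum((lm$screw_tip - apex)^2))
}

#' Tip-apex distance (TAD)
#'
#' Baumgaertner's two-term sum: the calibrated straight-line distance from
#' the screw tip to the femoral head apex in the AP view plus the same
#' distance in the LAT view, each view calibrated independently.
#'
#' @param case A [case_radiographs()] object.
#' @return TAD in mm.
#' @export
tad <- function(case) {
  tip_apex_term(case$ap, case$true_diameter_mm) +
    tip_apex_term(case$lat, case$true_diameter_mm)
}

#' Calcar-referenced tip-apex distance (Cal TAD)
#'
#' Moves the AP reference line inferiorly to the calcar: the AP term is the
#' calibrated distance from the screw tip to the intersection of the line
#' through the calcar point parallel to the neck axis with the head circle
#' (medial side).  The LAT term is identical to TAD's LAT term.
#'
#' @param case A [case_radiographs()] object whose AP view has a
#'   `calcar_point`.
#' @return Cal TAD in mm.
#' @export
cal_tad <- function(case) {
  ap <- case$ap
  if (is.null(ap$calcar_point))
    stop_mtad("missing_landmark", "calcar_point required for Cal TAD")
  ref <- tryCatch(
    line_circle_far_intersection(ap$calcar_point, ap$neck_axis_dir,
                                 ap$head_center, ap$head_radius),
    mtad_no_intersection = function(e)
      stop_mtad("invalid_landmark", "calcar axis does not intersect the head circle")
  )
  cal <- calibration_for_view(ap, case$true_diameter_mm)
  cal$scale * sqrt(sum((ap$screw_tip - ref$point)^2)) +
    tip_apex_term(case$lat, case$true_diameter_mm)
}

#' Modified tip-apex distance (mTAD)
#'
#' Direction-aware TAD variant.  In the AP view, point B is the far
#' intersection of the lag-screw axis with the head circle and C is the head
#' apex; the AP part is AB + sign * BC, where AB is the (calibrated)
#' distance from the tip A to B along the screw axis, BC the straight-line
#' chord from B to C, and sign is +1 when B lies superior to the neck
#' central axis, -1 when inferior, 0 on the axis.  The LAT part is the
#' traditional LAT tip-apex term.  An inferior screw therefore scores lower
#' than a superior screw with the same insertion depth; a central screw
#' reduces exactly to TAD.
#'
#' A negative AB (tip beyond the far head surface) is reported as-is with
#' `penetration = TRUE` rather than an error.
#'
#' @param case A [case_radiographs()] object.
#' @return A list: `mtad_mm`, and audit components `ap_part_mm`, `ab_mm`,
#'   `bc_mm` (unsigned), `bc_sign`, `lat_term_mm`, `penetration`.
#' @export
modified_tad <- function(case) {
  ap <- case$ap
  cal <- calibration_for_view(ap, case$true_diameter_mm)
  hit <- line_circle_far_intersection(ap$screw_tip, ap$screw_axis_dir,
                                      ap$head_center, ap$head_radius)
  B <- hit$point
  C <- apex_point(ap)
  ab <- cal$scale * hit$t
  bc <- cal$scale * sqrt(sum((B - C)^2))
  off <- cal$scale *
    signed_offset_from_axis(B, ap$neck_axis_point, ap$neck_axis_dir,
                            POSITIVE_SIDE)
  bc_sign <- if (abs(off) < 1e-6) 0 else sign(off)
  lat_term <- tip_apex_term(case$lat, case$true_diameter_mm)
  ap_part <- ab + bc_sign * bc
  list(mtad_mm = ap_part + lat_term, ap_part_mm = ap_part,
       ab_mm = ab, bc_mm = bc, bc_sign = bc_sign,
       lat_term_mm = lat_term, penetration = hit$t < 0)
}

#' Parker's ratio
#'
#' Position of the screw axis across the femoral head, as a percentage of
#' the head-circle diameter perpendicular to the neck axis.  0 corresponds
#' to the inferior (AP) or anterior (LAT) end of that diameter, 100 to the
#' opposite cortex, 50 to a screw axis through the head centre.  Values
#' outside [0, 100] indicate a screw axis crossing outside the head and are
#' returned unclamped with `out_of_range = TRUE`.
#'
#' @param case A [case_radiographs()] object.
#' @param view `"AP"` or `"LAT"`.
#' @return A list: `ratio_pct`, `out_of_range`.
#' @export
parker_ratio <- function(case, view = c("AP", "LAT")) {
  view <- match.arg(view)
  lm <- if (view == "AP") case$ap else case$lat
  n <- perp2(lm$neck_axis_dir)
  if (sum(n * POSITIVE_SIDE) < 0) n <- -n
  # crossing of the screw axis with the chord line {center + s n}
  d <- lm$screw_axis_dir
  denom <- d[1] * n[2] - d[2] * n[1]
  if (abs(denom) < 1e-12)
    stop_mtad("undefined_ratio", "screw axis parallel to the measurement chord")
  rel <- lm$head_center - lm$screw_tip
  u <- (rel[1] * n[2] - rel[2] * n[1]) / denom
  crossing <- lm$screw_tip + u * d
  s <- sum((crossing - lm$head_center) * n)
  r <- lm$head_radius
  # AP: 0 at the inferior (-n) end; LAT: 0 at the anterior (+n) end
  ratio <- if (view == "AP") 100 * (s + r) / (2 * r) else 100 * (r - s) / (2 * r)
  list(ratio_pct = ratio, out_of_range = ratio < 0 || ratio > 100)
}

#' Cleveland zone of the screw tip
#'
#' Classic 3 x 3 grid locating the tip within the head: rows from the AP
#' view (superior / central / inferior thirds of the signed offset from the
#' neck axis), columns from the LAT view (anterior / central / posterior
#' thirds).  Zone = 3 (row - 1) + col, so zone 1 is superior-anterior and
#' zone 5 centre-centre; the safe zones of the classic teaching are
#' \{5, 6, 8, 9\}.
#'
#' @param case A [case_radiographs()] object.
#' @return A list: `zone` (1-9), `row`, `col`, `out_of_head` (TRUE when the
#'   tip lies outside the head circle in either view; the zone of the
#'   nearest in-head position is still reported as a diagnostic).
#' @export
cleveland_zone <- function(case) {
  band <- function(lm) {
    off <- signed_offset_from_axis(lm$screw_tip, lm$neck_axis_point,
                                   lm$neck_axis_dir, POSITIVE_SIDE)
    third <- lm$head_radius / 3
    if (off > third) 1L else if (off >= -third) 2L else 3L
  }
  outside <- function(lm)
    sqrt(sum((lm$screw_tip - lm$head_center)^2)) > lm$head_radius * (1 + 1e-9)
  row <- band(case$ap)
  col <- band(case$lat)
  list(zone = 3L * (row - 1L) + col, row = row, col = col,
       out_of_head = outside(case$ap) || outside(case$lat))
}

#' Axis-blade angle (ABA)
#'
#' Signed AP-view angle between the femoral neck axis and the lag-screw
#' axis, in degrees.  Negative when the screw deviates superiorly from the
#' neck axis, positive when inferiorly, so the classic safety threshold
#' "ABA > -10" reads as "no more than 10 degrees of superior deviation".
#' Range (-90, 90).
#'
#' @param case A [case_radiographs()] object.
#' @return Signed angle in degrees.
#' @export
axis_blade_angle <- function(case) {
  ap <- case$ap
  nd <- ap$neck_axis_dir
  sd <- ap$screw_axis_dir
  cross <- nd[1] * sd[2] - nd[2] * sd[1]   # > 0: screw rotated toward superior
  dotp <- sum(nd * sd)
  -atan2(cross, dotp) * 180 / pi
}

#' Compute all six position parameters for a case
#'
#' Runs every metric with per-metric error capture: a metric whose
#' preconditions fail (e.g. a missing calcar point) is recorded as `NA` with
#' its error message, without aborting the remaining metrics.
#'
#' @param case A [case_radiographs()] object.
#' @return A one-row `data.frame` with columns `case_id`, `tad_mm`,
#'   `cal_tad_mm`, `mtad_mm`, `parker_ap_pct`, `parker_lat_pct`,
#'   `cleveland_zone`, `aba_deg`, audit components `ab_ap_mm`, `bc_ap_mm`,
#'   `bc_sign`, `penetration_flag`, `out_of_head_flag`, and per-metric error
#'   strings (`NA` when clean).
#' @export
compute_all_metrics <- function(case) {
  grab <- function(expr) {
    tryCatch(list(value = expr, error = NA_character_),
             mtad_error = function(e) list(value = NULL,
                                           error = conditionMessage(e)))
  }
  t_ <- grab(tad(case))
  ct <- grab(cal_tad(case))
  mt <- grab(modified_tad(case))
  pa <- grab(parker_ratio(case, "AP"))
  pl <- grab(parker_ratio(case, "LAT"))
  cz <- grab(cleveland_zone(case))
  ab <- grab(axis_blade_angle(case))
  num <- function(g, f = identity) if (is.null(g$value)) NA_real_ else f(g$value)
  data.frame(
    case_id = case$case_id,
    tad_mm = num(t_),
    cal_tad_mm = num(ct),
    mtad_mm = num(mt, function(v) v$mtad_mm),
    parker_ap_pct = num(pa, function(v) v$ratio_pct),
    parker_lat_pct = num(pl, function(v) v$ratio_pct),
    cleveland_zone = if (is.null(cz$value)) NA_integer_ else cz$value$zone,
    aba_deg = num(ab),
    ab_ap_mm = num(mt, function(v) v$ab_mm),
    bc_ap_mm = num(mt, function(v) v$bc_mm),
    bc_sign = num(mt, function(v) v$bc_sign),
    penetration_flag = if (is.null(mt$value)) NA else mt$value$penetration,
    out_of_head_flag = if (is.null(cz$value)) NA else cz$value$out_of_head,
    err_tad = t_$error, err_cal_tad = ct$error, err_mtad = mt$error,
    err_parker_ap = pa$error, err_parker_lat = pl$error,
    err_cleveland = cz$error, err_aba = ab$error,
    stringsAsFactors = FALSE
  )
}
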