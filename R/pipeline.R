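# End-to-end orchestration: landmark file I/O, batch measurement,
# statistical evaluation against outcomes, and safety-threshold flags.

LANDMARK_COLS <- c("case_id", "view", "side", "head_cx", "head_cy", "head_r",
                   "neck_px", "neck_py", "neck_dx", "neck_dy",
                   "tip_x", "tip_y", "screw_dx", "screw_dy",
                   "screw_diam_units", "calcar_x", "calcar_y")

#' Read a landmark table
#'
#' Accepts a CSV path or an already-loaded `data.frame` in the landmark
#' schema (one row per case per view; columns `case_id, view, side,
#' head_cx, head_cy, head_r, neck_px, neck_py, neck_dx, neck_dy, tip_x,
#' tip_y, screw_dx, screw_dy, screw_diam_units, calcar_x, calcar_y`).
#' Left hips (`side == "L"`) are normalised by mirroring x so that medial is
#' always +x.  Malformed rows (missing required fields, non-positive radius
#' or screw diameter, unknown view) are dropped with a warning; the number
#' skipped is attached as attribute `n_skipped`.
#'
#' @param x CSV file path or `data.frame`.
#' @return A validated, side-normalised landmark `data.frame`.
#' @export
read_landmarks <- function(x) {
  df <- if (is.character(x)) {
    if (!file.exists(x)) stop_mtad("io", paste("cannot read", x))
    utils::read.csv(x, stringsAsFactors = FALSE)
  } else as.data.frame(x)
  missing_cols <- setdiff(LANDMARK_COLS, names(df))
  if (length(missing_cols))
    stop_mtad("io", paste("landmark table missing columns:",
                          paste(missing_cols, collapse = ", ")))
  df <- df[LANDMARK_COLS]
  num_cols <- setdiff(LANDMARK_COLS, c("case_id", "view", "side"))
  for (cc in num_cols) df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  required <- setdiff(num_cols, c("calcar_x", "calcar_y"))
  ok <- df$view %in% c("AP", "LAT") &
    stats::complete.cases(df[required]) &
    df$head_r > 0 & df$screw_diam_units > 0
  ok[is.na(ok)] <- FALSE
  if (any(!ok))
    warning(sprintf("skipping %d malformed landmark row(s): %s",
                    sum(!ok), paste(utils::head(which(!ok), 10), collapse = ", ")))
  df <- df[ok, , drop = FALSE]
  # mirror left hips so medial is +x in every stored row
  left <- !is.na(df$side) & df$side == "L"
  for (cc in c("head_cx", "neck_px", "tip_x", "calcar_x", "neck_dx", "screw_dx"))
    df[[cc]][left] <- -df[[cc]][left]
  df$side[left] <- "R"
  attr(df, "n_skipped") <- sum(!ok)
  df
}

# one landmark row -> view_landmarks
row_to_view <- function(r) {
  calcar <- if (is.finite(r$calcar_x) && is.finite(r$calcar_y))
    c(r$calcar_x, r$calcar_y) else NULL
  view_landmarks(r$view,
                 head_center = c(r$head_cx, r$head_cy), head_radius = r$head_r,
                 neck_axis_point = c(r$neck_px, r$neck_py),
                 neck_axis_dir = c(r$neck_dx, r$neck_dy),
                 screw_tip = c(r$tip_x, r$tip_y),
                 screw_axis_dir = c(r$screw_dx, r$screw_dy),
                 screw_diameter_measured = r$screw_diam_units,
                 calcar_point = calcar)
}

#' Assemble paired cases from a landmark table
#'
#' @param landmarks Output of [read_landmarks()].
#' @param true_diameter_mm Calibration reference (default 12.5 mm).
#' @return A named list of [case_radiographs()] objects; cases lacking
#'   either view are dropped with a warning.
#' @export
landmarks_to_cases <- function(landmarks, true_diameter_mm = 12.5) {
  ids <- factor(landmarks$case_id, levels = unique(landmarks$case_id))
  chunks <- split(seq_len(nrow(landmarks)), ids)
  out <- vector("list", length(chunks))
  names(out) <- names(chunks)
  dropped <- character(0)
  for (id in names(chunks)) {
    sub <- landmarks[chunks[[id]], , drop = FALSE]
    iap <- which(sub$view == "AP")
    ilat <- which(sub$view == "LAT")
    if (length(iap) != 1L || length(ilat) != 1L) {
      dropped <- c(dropped, id)
      next
    }
    out[[id]] <- case_radiographs(
      sub$case_id[1], row_to_view(as.list(sub[iap, ])),
      row_to_view(as.list(sub[ilat, ])),
      true_diameter_mm = true_diameter_mm)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(dropped))
    warning(sprintf("dropping %d case(s) without a full AP+LAT pair: %s",
                    length(dropped),
                    paste(utils::head(dropped, 10), collapse = ", ")))
  out
}

#' Batch-compute position metrics
#'
#' Runs [compute_all_metrics()] for every complete AP+LAT case in a
#' landmark table (or list of cases); per-metric errors are recorded in the
#' output rather than aborting the batch.
#'
#' @param landmarks Landmark CSV path, landmark `data.frame`, or a list of
#'   [case_radiographs()] objects.
#' @param true_diameter_mm Calibration reference (default 12.5 mm).
#' @return A metrics `data.frame`, one row per case.
#' @export
run_measure <- function(landmarks, true_diameter_mm = 12.5) {
  cases <- if (is.list(landmarks) && !is.data.frame(landmarks) &&
               all(vapply(landmarks, inherits, logical(1), "case_radiographs")))
    landmarks
  else landmarks_to_cases(read_landmarks(landmarks), true_diameter_mm)
  if (!length(cases)) {
    warning("no measurable cases")
    return(empty_metrics_frame())
  }
  do.call(rbind, lapply(cases, compute_all_metrics))
}

empty_metrics_frame <- function() {
  compute_all_metrics(generate_worked_example())[0, ]
}

#' Evaluate position parameters against the cut-out outcome
#'
#' The statistical comparison of a cut-out study: one ROC analysis
#' (AUC, DeLong CI, Mann-Whitney p, Youden cut-off with sensitivity and
#' specificity) per continuous parameter, chi-square/exact association
#' tests for the categorical covariates and Cleveland-zone-1 membership,
#' and frequency summaries.  Deterministic given its inputs.
#'
#' @param metrics Metrics `data.frame` from [run_measure()] (or a cohort's
#'   `$metrics`).
#' @param outcomes `data.frame` with `case_id`, `cutout` (logical/0-1) and
#'   optional covariates `pattern`, `reduction`, `singh`.
#' @param parameters Continuous parameters to evaluate (default all six).
#' @return A list: `roc_table` (one row per parameter, Table-3-like
#'   columns), `associations` (covariate chi-square rows), `proportions`,
#'   and `roc_results` (the full `roc_result` objects, named).
#' @export
run_evaluate <- function(metrics, outcomes,
                         parameters = c("tad_mm", "cal_tad_mm", "mtad_mm",
                                        "parker_ap_pct", "parker_lat_pct",
                                        "aba_deg")) {
  d <- merge(metrics, outcomes, by = "case_id")
  if (!nrow(d)) stop_mtad("io", "metrics and outcomes share no case_id")
  d$cutout <- as.logical(d$cutout)
  if (all(d$cutout) || !any(d$cutout))
    stop_mtad("degenerate_outcome",
              "outcome shows no variation (all or no cut-outs)")
  roc_results <- list()
  rows <- list()
  for (p in parameters) {
    rr <- roc_analysis(d[[p]], d$cutout, parameter_name = p)
    roc_results[[p]] <- rr
    rows[[p]] <- data.frame(
      parameter = p, auc = round(rr$auc, 3), p_value = rr$p_value,
      ci_low = round(rr$ci_low, 3), ci_high = round(rr$ci_high, 3),
      cutoff = rr$cutoff, cutoff_reported = rr$cutoff_reported,
      sensitivity_pct = round(rr$sensitivity_pct, 1),
      specificity_pct = round(rr$specificity_pct, 1),
      higher_is_risk = rr$higher_is_risk,
      n_pos = rr$n_pos, n_neg = rr$n_neg, stringsAsFactors = FALSE)
  }
  assoc <- list()
  add_assoc <- function(name, fac) {
    fac <- as.factor(fac)
    if (nlevels(droplevels(fac)) < 2L) return()
    tab <- table(droplevels(fac), factor(d$cutout, c(TRUE, FALSE), c("Y", "N")))
    ct <- chi_square_test(unclass(tab))
    assoc[[name]] <<- data.frame(
      covariate = name, statistic = round(ct$statistic, 2), df = ct$df,
      p_value = ct$p_value, method = ct$method_used, stringsAsFactors = FALSE)
  }
  if ("pattern" %in% names(d)) add_assoc("pattern", d$pattern)
  if ("reduction" %in% names(d)) add_assoc("reduction", d$reduction)
  if ("cleveland_zone" %in% names(d))
    add_assoc("cleveland_zone1", ifelse(d$cleveland_zone == 1L,
                                        "zone1", "other"))
  prop <- data.frame(
    quantity = "cutout_rate",
    count = sum(d$cutout), total = nrow(d),
    percent = proportion_summary(sum(d$cutout), nrow(d)),
    stringsAsFactors = FALSE)
  list(roc_table = do.call(rbind, rows),
       associations = if (length(assoc)) do.call(rbind, assoc) else NULL,
       proportions = prop,
       roc_results = roc_results)
}

#' Default safety thresholds
#'
#' The published protective recommendations: TAD < 25 mm (Baumgaertner),
#' modified TAD <= 25 mm, axis-blade angle > -10 degrees (Mao), Cleveland
#' safe zones \{5, 6, 8, 9\}.
#' @return Named list of thresholds.
#' @export
default_thresholds <- function() {
  list(mtad_max = 25, tad_max = 25, aba_min = -10,
       safe_zones = c(5L, 6L, 8L, 9L))
}

#' Per-case safety flags
#'
#' Applies the protective-threshold rules to each case's metrics.  Note the
#' inequality forms differ: the modified-TAD rule is inclusive
#' (`mtad <= 25` passes) while the classic TAD rule is strict
#' (`tad < 25`).  A missing metric yields an `NA` flag without affecting
#' the others.
#'
#' @param metrics Metrics `data.frame` from [run_measure()].
#' @param thresholds Rule set, see [default_thresholds()].
#' @return A `data.frame` with one logical column per rule plus `all_pass`;
#'   attribute `summary` holds pass counts per rule.
#' @export
run_flags <- function(metrics, thresholds = default_thresholds()) {
  out <- data.frame(
    case_id = metrics$case_id,
    flag_mtad = metrics$mtad_mm <= thresholds$mtad_max,
    flag_tad = metrics$tad_mm < thresholds$tad_max,
    flag_aba = metrics$aba_deg > thresholds$aba_min,
    flag_zone = metrics$cleveland_zone %in% thresholds$safe_zones &
      !is.na(metrics$cleveland_zone),
    stringsAsFactors = FALSE)
  out$flag_zone[is.na(metrics$cleveland_zone)] <- NA
  out$all_pass <- out$flag_mtad & out$flag_tad & out$flag_aba & out$flag_zone
  attr(out, "summary") <- vapply(
    out[c("flag_mtad", "flag_tad", "flag_aba", "flag_zone", "all_pass")],
    function(z) sum(z, na.rm = TRUE), integer(1))
  out
}
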