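#' RTOG/NRG volume-specific guideline thresholds
#'
#' The PTV-volume-specific deviation thresholds shared by RTOG 0813,
#' RTOG 0915 and NRG-BR001 for SBRT lung planning, together with the
#' volume-independent limits. For the conformality index (CI), R50 and D2cm,
#' a value below the "none" limit is no deviation, a value in the closed
#' minor band is a minor deviation, and a value above the band is a major
#' deviation. Thresholds at intermediate PTV volumes are obtained by linear
#' interpolation (see [interpolate_thresholds()]).
#'
#' @param rows data frame of threshold rows; defaults to the protocol table
#'   (11 volumes from 1.8 to 163 cc). Columns: `ptv_cc`, `ci_none`,
#'   `ci_minor_upper`, `r50_none`, `r50_minor_upper`, `d2cm_none`,
#'   `d2cm_minor_upper` (D2cm in % of Rx).
#' @param v100_target_pct coverage target: percent of PTV receiving Rx.
#' @param v90_min_pct minimum percent of PTV receiving 90% of Rx.
#' @param v105_max_pct maximum hot volume outside the PTV above 105% of Rx,
#'   as percent of PTV volume.
#' @param rx_over_dmax_range allowed range of Rx / maximum dose.
#' @param d95_target_pct target D95 as percent of Rx.
#' @param chestwall_v30_max_cc,lung_v20_max_pct organ-at-risk checks.
#' @return Object of class `guideline_set`.
#' @export
rtog_guidelines <- function(rows = rtog_table1(),
                            v100_target_pct = 95,
                            v90_min_pct = 99,
                            v105_max_pct = 15,
                            rx_over_dmax_range = c(0.60, 0.90),
                            d95_target_pct = 100,
                            chestwall_v30_max_cc = 30,
                            lung_v20_max_pct = 10) {
  stopifnot(is.data.frame(rows), nrow(rows) >= 2,
            all(diff(rows$ptv_cc) > 0),
            all(rows$ci_none < rows$ci_minor_upper),
            all(rows$r50_none < rows$r50_minor_upper),
            all(rows$d2cm_none < rows$d2cm_minor_upper))
  stopifnot(rx_over_dmax_range[1] < rx_over_dmax_range[2])
  structure(list(rows = rows,
                 v100_target_pct = v100_target_pct,
                 v90_min_pct = v90_min_pct,
                 v105_max_pct = v105_max_pct,
                 rx_over_dmax_range = rx_over_dmax_range,
                 d95_target_pct = d95_target_pct,
                 chestwall_v30_max_cc = chestwall_v30_max_cc,
                 lung_v20_max_pct = lung_v20_max_pct),
            class = "guideline_set")
}

#' @rdname rtog_guidelines
#' @export
rtog_table1 <- function() {
  data.frame(
    ptv_cc          = c(1.8, 3.8, 7.4, 13.2, 22, 34, 50, 70, 95, 126, 163),
    ci_none         = rep(1.2, 11),
    ci_minor_upper  = rep(1.5, 11),
    # the 13.2-50 cc dose-falloff limits carry the protocol's exact
    # values (4.7/4.5/4.3/4.0), which the printed summary table rounds
    r50_none        = c(6, 6, 5, 4.7, 4.5, 4.3, 4.0, 4, 3, 3, 3),
    r50_minor_upper = c(7.5, 6.5, 6, 5.8, 5.5, 5.3, 5, 4.8, 4.4, 4, 3.7),
    d2cm_none       = c(50, 50, 50, 50, 54, 58, 62, 66, 70, 73, 77),
    d2cm_minor_upper = c(57, 57, 58, 58, 63, 68, 77, 86, 89, 91, 94))
}

#' Interpolate guideline thresholds at a PTV volume
#'
#' Piecewise-linear interpolation of each threshold column between the
#' bracketing table rows, clamped to the first/last row outside the
#' tabulated volume range.
#'
#' @param set a [rtog_guidelines()] object.
#' @param ptv_cc PTV volume, cc (> 0).
#' @return Named list of class `guideline_row` with the interpolated
#'   thresholds and the volume they were evaluated at.
#' @export
interpolate_thresholds <- function(set, ptv_cc) {
  stopifnot(inherits(set, "guideline_set"), is.numeric(ptv_cc), ptv_cc > 0)
  rows <- set$rows
  cols <- c("ci_none", "ci_minor_upper", "r50_none", "r50_minor_upper",
            "d2cm_none", "d2cm_minor_upper")
  out <- lapply(cols, function(cl)
    stats::approx(rows$ptv_cc, rows[[cl]], xout = ptv_cc, rule = 2)$y)
  names(out) <- cols
  out$ptv_cc <- ptv_cc
  structure(out, class = "guideline_row")
}

#' Normalised D2cm (D'2cm)
#'
#' Measured D2cm divided by the PTV-volume-interpolated dose level at which
#' a minor deviation begins (the none/minor boundary). A value below 1.0
#' meets the guideline; 1.0 or more is a deviation.
#'
#' @param d2cm_measured measured D2cm, percent of Rx.
#' @param d2cm_none_threshold none/minor boundary, percent of Rx (> 0).
#' @return Dimensionless ratio.
#' @export
d2cm_prime <- function(d2cm_measured, d2cm_none_threshold) {
  if (any(d2cm_none_threshold <= 0))
    stop("invalid threshold: none/minor boundary must be positive",
         call. = FALSE)
  d2cm_measured / d2cm_none_threshold
}

#' Normalised R50 (R50')
#'
#' Measured R50 divided by the interpolated R50 value at which a minor
#' deviation begins; below 1.0 meets the guideline.
#'
#' @param r50_measured measured R50.
#' @param r50_none_threshold none/minor boundary (> 0).
#' @return Dimensionless ratio.
#' @export
r50_prime <- function(r50_measured, r50_none_threshold) {
  if (any(r50_none_threshold <= 0))
    stop("invalid threshold: none/minor boundary must be positive",
         call. = FALSE)
  r50_measured / r50_none_threshold
}

# three-band classification for a volume-specific metric; the minor band is
# closed on both ends ("None <50, Minor 50-57" in the protocol table)
classify_banded <- function(value, none_limit, minor_upper) {
  if (is.na(value)) return(NA_character_)
  if (value < none_limit) "none"
  else if (value <= minor_upper) "minor"
  else "major"
}

#' Classify a plan's metrics against the guidelines
#'
#' Volume-specific metrics (CI, R50, D2cm) are classified none / minor /
#' major against thresholds interpolated at the plan's PTV volume;
#' volume-independent metrics (V100%, V90%, V105%, Rx/Dmax) are pass /
#' deviation only, mirroring the protocols.
#'
#' @param metrics a [plan_metrics()] object (or named list with fields
#'   `ptv_cc`, `ci`, `r50`, `d2cm_pct`, `v100_pct`, `v90_pct`,
#'   `v105_pct_of_ptv`, `rx_over_dmax`).
#' @param set a [rtog_guidelines()] object.
#' @return Object of class `deviation_report`: per-metric classes, the
#'   interpolated thresholds used, normalised D'2cm/R50', and flags for any
#'   missing metrics.
#' @export
classify_plan <- function(metrics, set = rtog_guidelines()) {
  stopifnot(inherits(set, "guideline_set"))
  need <- c("ptv_cc", "ci", "r50", "d2cm_pct", "v100_pct", "v90_pct",
            "v105_pct_of_ptv", "rx_over_dmax")
  missing_fields <- need[vapply(need, function(f)
    is.null(metrics[[f]]) || is.na(metrics[[f]]), logical(1))]
  if (is.null(metrics$ptv_cc) || is.na(metrics$ptv_cc))
    stop("cannot classify without a PTV volume", call. = FALSE)
  thr <- interpolate_thresholds(set, metrics$ptv_cc)

  get <- function(f) if (f %in% missing_fields) NA_real_ else metrics[[f]]
  banded <- list(
    ci   = classify_banded(get("ci"), thr$ci_none, thr$ci_minor_upper),
    r50  = classify_banded(get("r50"), thr$r50_none, thr$r50_minor_upper),
    d2cm = classify_banded(get("d2cm_pct"), thr$d2cm_none,
                           thr$d2cm_minor_upper))
  pass_fail <- list(
    v100 = if (is.na(get("v100_pct"))) NA_character_ else
      if (get("v100_pct") >= set$v100_target_pct) "none" else "deviation",
    v90 = if (is.na(get("v90_pct"))) NA_character_ else
      if (get("v90_pct") >= set$v90_min_pct) "none" else "deviation",
    v105 = if (is.na(get("v105_pct_of_ptv"))) NA_character_ else
      if (get("v105_pct_of_ptv") < set$v105_max_pct) "none" else "deviation",
    rx_over_dmax = if (is.na(get("rx_over_dmax"))) NA_character_ else
      if (get("rx_over_dmax") >= set$rx_over_dmax_range[1] &&
          get("rx_over_dmax") <= set$rx_over_dmax_range[2]) "none"
      else "deviation")

  structure(list(
    banded = banded,
    pass_fail = pass_fail,
    thresholds = thr,
    d2cm_prime = if (is.na(get("d2cm_pct"))) NA_real_ else
      d2cm_prime(get("d2cm_pct"), thr$d2cm_none),
    r50_prime = if (is.na(get("r50"))) NA_real_ else
      r50_prime(get("r50"), thr$r50_none),
    missing = missing_fields),
    class = "deviation_report")
}

#' @export
print.guideline_row <- function(x, ...) {
  cat(sprintf("guideline thresholds at PTV %.2f cc:\n", x$ptv_cc))
  cat(sprintf("  CI   none < %.3f, minor <= %.3f\n", x$ci_none,
              x$ci_minor_upper))
  cat(sprintf("  R50  none < %.3f, minor <= %.3f\n", x$r50_none,
              x$r50_minor_upper))
  cat(sprintf("  D2cm none < %.1f%%, minor <= %.1f%% of Rx\n", x$d2cm_none,
              x$d2cm_minor_upper))
  invisible(x)
}

#' @export
print.deviation_report <- function(x, ...) {
  cat("deviation report (volume-specific):\n")
  for (m in names(x$banded))
    cat(sprintf("  %-5s %s\n", toupper(m), x$banded[[m]]))
  cat(sprintf("  D'2cm = %.3f, R50' = %.3f\n", x$d2cm_prime, x$r50_prime))
  cat("volume-independent:\n")
  for (m in names(x$pass_fail))
    cat(sprintf("  %-13s %s\n", m, x$pass_fail[[m]]))
  if (length(x$missing))
    cat("missing metrics:", paste(x$missing, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.guideline_set <- function(x, ...) {
  cat("<guideline_set>\n")
  cat(sprintf("  V100 target %.1f%%, V90 >= %.1f%%, V105 < %.1f%% of PTV, Rx/Dmax in [%.2f, %.2f]\n",
              x$v100_target_pct, x$v90_min_pct, x$v105_max_pct,
              x$rx_over_dmax_range[1], x$rx_over_dmax_range[2]))
  print(x$rows, row.names = FALSE)
  invisible(x)
}
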