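#' Compute the full per-plan metric vector
#'
#' Evaluates every plan-quality metric used in RTOG/NRG SBRT lung
#' evaluation on a single plan: PTV volume, D95%, V100%, V90%, near-minimum
#' dose to 0.03 cc, maximum dose, Rx/Dmax, V105% outside the PTV,
#' conformality index, R50, D2cm, the volume-normalised D'2cm and R50', MU,
#' and the island-type flag.
#'
#' All percent-dose quantities are relative to the prescription; V100/V90
#' are percent of PTV volume receiving 100%/90% of Rx (inclusive), V105 is
#' the volume outside the PTV above 105% of Rx (strict) in percent of PTV
#' volume.
#'
#' @param plan an [sbrt_plan()].
#' @param set a [rtog_guidelines()] object used for the D'2cm/R50'
#'   denominators.
#' @param dist optional precomputed PTV [distance_from_mask()] field (the
#'   expensive step; reuse it across a patient's arms).
#' @param island_threshold_mm chest-wall distance defining island-type
#'   targets, mm.
#' @param chestwall_dist optional precomputed chest-wall
#'   [distance_from_mask()] field (reusable across patients sharing a grid).
#' @return One-row data frame of class `plan_metrics`.
#' @export
plan_metrics <- function(plan, set = rtog_guidelines(), dist = NULL,
                         island_threshold_mm = 10, chestwall_dist = NULL) {
  stopifnot(inherits(plan, "sbrt_plan"))
  issues <- validate_plan(plan)
  if (length(issues) > 0)
    stop("invalid plan: ", paste(issues, collapse = "; "), call. = FALSE)
  grid <- plan$dose
  ptv <- plan$masks$PTV
  body <- plan$masks$body
  rx <- plan$rx_gy

  s <- dose_sample(grid, ptv)
  ptv_cc <- structure_volume_cc(ptv)
  d95 <- dose_at_volume_pct(s, 95)
  dmax <- max_dose(grid, body)
  if (is.null(dist)) dist <- distance_from_mask(ptv)

  ci_val <- conformality_index(grid, ptv, rx, body)
  r50_val <- r50(grid, ptv, rx, body)
  d2cm_val <- d2cm(grid, ptv, rx, margin_mm = 20, body = body, dist = dist)
  thr <- interpolate_thresholds(set, ptv_cc)

  island <- classify_island(ptv, plan$masks$chestwall,
                            threshold_mm = island_threshold_mm,
                            dist = chestwall_dist)

  out <- data.frame(
    patient_id = plan$patient_id,
    arm = plan$arm,
    algorithm = plan$algorithm,
    ptv_cc = ptv_cc,
    d95_pct = 100 * d95 / rx,
    v100_pct = volume_pct_at_dose(s, rx),
    v90_pct = volume_pct_at_dose(s, 0.9 * rx),
    dmin_pct = 100 * near_min_dose(s, 0.03) / rx,
    dmax_pct = 100 * dmax / rx,
    rx_over_dmax = rx / dmax,
    v105_pct_of_ptv = hot_volume_outside_pct(grid, ptv, 1.05 * rx),
    ci = ci_val,
    r50 = r50_val,
    d2cm_pct = d2cm_val,
    d2cm_prime = d2cm_prime(d2cm_val, thr$d2cm_none),
    r50_prime = r50_prime(r50_val, thr$r50_none),
    mu_total = plan$mu_total,
    island = island,
    stringsAsFactors = FALSE)
  class(out) <- c("plan_metrics", "data.frame")
  out
}

#' @export
print.plan_metrics <- function(x, ...) {
  cat(sprintf("<plan_metrics> patient %s, %s arm (%s), PTV %.2f cc%s\n",
              x$patient_id, x$arm, x$algorithm, x$ptv_cc,
              if (isTRUE(x$island)) ", island-type" else ""))
  cat(sprintf("  D95 %.2f%%  V100 %.2f%%  V90 %.2f%%  Dmin(0.03cc) %.1f%%  Rx/Dmax %.3f\n",
              x$d95_pct, x$v100_pct, x$v90_pct, x$dmin_pct, x$rx_over_dmax))
  cat(sprintf("  V105 %.2f%%  CI %.3f  R50 %.3f  D2cm %.1f%%  D'2cm %.3f  R50' %.3f  MU %.1f\n",
              x$v105_pct_of_ptv, x$ci, x$r50, x$d2cm_pct, x$d2cm_prime,
              x$r50_prime, x$mu_total))
  invisible(x)
}
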