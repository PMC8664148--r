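#' Renormalize a plan to a PTV coverage target
#'
#' Globally rescales the dose grid (and the monitor units with it) so that
#' the dose covering `coverage_target_pct` of the PTV equals the
#' prescription — the recalculate-then-renormalize workflow in which beam
#' weights are left untouched and only the plan normalization changes. The
#' relative spatial dose distribution is unchanged.
#'
#' @param plan an [sbrt_plan()].
#' @param coverage_target_pct percent of PTV volume to cover with Rx
#'   (default 95, i.e. restore D95% = 100% of Rx).
#' @return List with elements `plan` (the rescaled plan, arm set to
#'   `"renormalized"`) and `result` (class `renormalization`: scale factor,
#'   MU and D95 before/after).
#' @export
renormalize <- function(plan, coverage_target_pct = 95) {
  stopifnot(inherits(plan, "sbrt_plan"))
  s <- dose_sample(plan$dose, plan$masks$PTV)
  d_cov <- dose_at_volume_pct(s, coverage_target_pct)
  if (d_cov <= 0)
    stop("cannot renormalize: dose at the coverage target is zero",
         call. = FALSE)
  scale <- plan$rx_gy / d_cov
  new_plan <- plan
  new_plan$dose$values <- plan$dose$values * scale
  new_plan$mu_total <- plan$mu_total * scale
  new_plan$arm <- "renormalized"
  d_after <- dose_at_volume_pct(dose_sample(new_plan$dose, plan$masks$PTV),
                                coverage_target_pct)
  result <- structure(list(
    scale_factor = scale,
    mu_before = plan$mu_total,
    mu_after = new_plan$mu_total,
    d95_before_pct = 100 * d_cov / plan$rx_gy,
    d95_after_pct = 100 * d_after / plan$rx_gy,
    coverage_target_pct = coverage_target_pct),
    class = "renormalization")
  list(plan = new_plan, result = result)
}

#' @export
print.renormalization <- function(x, ...) {
  cat(sprintf("renormalization to D%g = Rx: scale %.5f\n",
              x$coverage_target_pct, x$scale_factor))
  cat(sprintf("  D95 %.2f%% -> %.2f%% of Rx;  MU %.1f -> %.1f (%+.2f%%)\n",
              x$d95_before_pct, x$d95_after_pct, x$mu_before, x$mu_after,
              100 * (x$scale_factor - 1)))
  invisible(x)
}
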