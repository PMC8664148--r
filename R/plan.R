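#' SBRT treatment plan
#'
#' Bundles a dose grid, structure masks sharing its geometry, and plan-level
#' bookkeeping (prescription, fractionation, monitor units, dose-calculation
#' algorithm, and which arm of the workflow the plan belongs to).
#'
#' @param dose a [dose_grid()].
#' @param masks named list of [structure_mask()] objects; must contain `PTV`.
#'   Recognised optional labels: `chestwall`, `lung_ipsi`, `lung_contra`,
#'   `body`.
#' @param rx_gy prescription dose, Gy (> 0).
#' @param n_fractions number of fractions.
#' @param mu_total total monitor units (> 0).
#' @param algorithm dose engine label, `"AAA"` or `"AXB"`.
#' @param arm workflow arm: `"plan"` (original), `"recalculated"`, or
#'   `"renormalized"`.
#' @param patient_id optional identifier carried into cohort tables.
#' @return An object of class `sbrt_plan`.
#' @export
sbrt_plan <- function(dose, masks, rx_gy, n_fractions = 5, mu_total,
                      algorithm = c("AAA", "AXB"),
                      arm = c("plan", "recalculated", "renormalized"),
                      patient_id = NA_character_) {
  algorithm <- match.arg(algorithm)
  arm <- match.arg(arm)
  if (inherits(masks, "structure_mask")) masks <- list(PTV = masks)
  if (is.null(names(masks)) || any(!nzchar(names(masks))))
    stop("`masks` must be a named list", call. = FALSE)
  plan <- structure(
    list(dose = dose, masks = masks, rx_gy = rx_gy,
         n_fractions = n_fractions, mu_total = mu_total,
         algorithm = algorithm, arm = arm, patient_id = patient_id),
    class = "sbrt_plan")
  issues <- validate_plan(plan)
  if (length(issues) > 0)
    stop("invalid plan: ", paste(issues, collapse = "; "), call. = FALSE)
  plan
}

#' Validate a plan's geometry and bookkeeping
#'
#' Report-based validation: returns a character vector of problems (empty if
#' the plan is usable) rather than raising an error, so that partially built
#' plans can be inspected.
#'
#' @param plan an `sbrt_plan` (or a bare list with the same fields).
#' @return Character vector of class `plan_validation`; length 0 means valid.
#' @export
validate_plan <- function(plan) {
  issues <- character(0)
  if (!inherits(plan$dose, "dose_grid"))
    issues <- c(issues, "dose is not a dose_grid")
  if (is.null(plan$masks$PTV))
    issues <- c(issues, "missing PTV mask")
  if (inherits(plan$dose, "dose_grid")) {
    for (nm in names(plan$masks)) {
      m <- plan$masks[[nm]]
      if (!inherits(m, "structure_mask")) {
        issues <- c(issues, sprintf("mask '%s' is not a structure_mask", nm))
      } else if (!same_geometry(plan$dose, m)) {
        issues <- c(issues, sprintf(
          "geometry mismatch: mask '%s' does not share the dose grid's shape/spacing/origin",
          nm))
      }
    }
  }
  if (!is.null(plan$masks$PTV) && inherits(plan$masks$PTV, "structure_mask") &&
      sum(plan$masks$PTV$voxels) == 0L)
    issues <- c(issues, "PTV mask is empty")
  if (!is.numeric(plan$rx_gy) || length(plan$rx_gy) != 1 ||
      !is.finite(plan$rx_gy) || plan$rx_gy <= 0)
    issues <- c(issues, "invalid prescription: rx_gy must be a positive number")
  if (!is.numeric(plan$mu_total) || length(plan$mu_total) != 1 ||
      !is.finite(plan$mu_total) || plan$mu_total <= 0)
    issues <- c(issues, "invalid MU: mu_total must be a positive number")
  structure(issues, class = c("plan_validation", "character"))
}

#' @export
print.plan_validation <- function(x, ...) {
  if (length(x) == 0) cat("plan OK: no issues found\n")
  else cat("plan issues:\n", paste0("  - ", x, collapse = "\n"), "\n", sep = "")
  invisible(x)
}

#' @export
print.sbrt_plan <- function(x, ...) {
  cat(sprintf("<sbrt_plan> patient %s | %s arm, %s | Rx %.2f Gy in %d fx | %.1f MU\n",
              x$patient_id, x$arm, x$algorithm, x$rx_gy, x$n_fractions,
              x$mu_total))
  cat(sprintf("  masks: %s\n", paste(names(x$masks), collapse = ", ")))
  print(x$dose)
  invisible(x)
}
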