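metric_cols_scaled <- c("d95_pct", "v100_pct", "v90_pct", "rx_over_dmax",
                        "v105_pct_of_ptv", "ci", "d2cm_prime", "r50_prime")

#' Per-metric cohort-mean scaling factors
#'
#' For each metric, the ratio of the recalculated-arm cohort mean to the
#' original-plan-arm cohort mean. These ratios drive the derivation of
#' algorithm-adapted guideline limits: the D2cm and R50 thresholds are
#' scaled by the ratios of the volume-normalised D'2cm and R50' (the forms
#' comparable across PTV sizes), CI by the raw CI ratio, and the
#' volume-independent limits by their own ratios.
#'
#' @param plan_means,recalc_means named numeric vectors of cohort means for
#'   (a subset of) `d95_pct`, `v100_pct`, `v90_pct`, `rx_over_dmax`,
#'   `v105_pct_of_ptv`, `ci`, `d2cm_prime`, `r50_prime`.
#' @param n number of paired patients behind the means (bookkeeping).
#' @return Object of class `scaling_factors`.
#' @export
scaling_factors <- function(plan_means, recalc_means, n = NA_integer_) {
  common <- intersect(names(plan_means), names(recalc_means))
  common <- intersect(common, metric_cols_scaled)
  if (length(common) == 0)
    stop("no shared metric names between the two mean vectors", call. = FALSE)
  pm <- plan_means[common]
  rm_ <- recalc_means[common]
  ratios <- ifelse(pm != 0, rm_ / pm, NA_real_)
  structure(list(ratios = ratios, plan_means = pm, recalc_means = rm_,
                 n = n), class = "scaling_factors")
}

#' Cohort-mean metric ratios from a paired cohort table
#'
#' @param cohort a cohort metrics table (see [generate_cohort()] /
#'   [read_cohort_csv()]) containing paired `plan` and `recalculated` rows
#'   for every patient.
#' @param arms character length-2: the reference and comparison arm labels.
#' @return A [scaling_factors()] object.
#' @export
cohort_ratios <- function(cohort, arms = c("plan", "recalculated")) {
  stopifnot(is.data.frame(cohort), all(arms %in% cohort$arm))
  a <- cohort[cohort$arm == arms[1], ]
  b <- cohort[cohort$arm == arms[2], ]
  unpaired <- c(setdiff(a$patient_id, b$patient_id),
                setdiff(b$patient_id, a$patient_id))
  if (length(unpaired) > 0)
    stop("pairing error: patients without both arms: ",
         paste(unique(unpaired), collapse = ", "), call. = FALSE)
  cols <- intersect(metric_cols_scaled, names(cohort))
  scaling_factors(colMeans(a[cols]), colMeans(b[cols]), n = nrow(a))
}

#' Scaled volume-independent guideline limits
#'
#' Applies the cohort-mean ratios to the volume-independent limits: the V90
#' and V105 limits and the Rx/Dmax bounds are the current limits times their
#' metric's ratio; the D95/V100 recommendations are the recalculated-arm
#' cohort means themselves. Percent-scale limits are rounded to 1 decimal,
#' ratio-scale limits to 2 decimals.
#'
#' @param current a [rtog_guidelines()] object holding the current limits.
#' @param r a [scaling_factors()] object.
#' @return Data frame with columns `metric`, `current`, `proposed`.
#' @export
scale_volume_independent <- function(current, r) {
  stopifnot(inherits(current, "guideline_set"), inherits(r, "scaling_factors"))
  need <- c("d95_pct", "v100_pct", "v90_pct", "v105_pct_of_ptv",
            "rx_over_dmax")
  miss <- setdiff(need, names(r$ratios))
  if (length(miss) > 0)
    stop("incomplete derivation: missing ratios for ",
         paste(miss, collapse = ", "), call. = FALSE)
  rat <- r$ratios
  cur <- c(d95_pct = current$d95_target_pct,
           v100_pct = current$v100_target_pct,
           v90_pct = current$v90_min_pct,
           v105_pct_of_ptv = current$v105_max_pct,
           rx_over_dmax_min = current$rx_over_dmax_range[1],
           rx_over_dmax_max = current$rx_over_dmax_range[2])
  prop <- c(
    # coverage recommendations track the recalculated-arm means directly
    d95_pct = round_half_up(r$recalc_means[["d95_pct"]] *
                              current$d95_target_pct /
                              r$plan_means[["d95_pct"]], 1),
    v100_pct = round_half_up(r$recalc_means[["v100_pct"]] *
                               current$v100_target_pct /
                               r$plan_means[["v100_pct"]], 1),
    v90_pct = round_half_up(cur[["v90_pct"]] * rat[["v90_pct"]], 1),
    v105_pct_of_ptv = round_half_up(cur[["v105_pct_of_ptv"]] *
                                      rat[["v105_pct_of_ptv"]], 1),
    rx_over_dmax_min = round_half_up(cur[["rx_over_dmax_min"]] *
                                       rat[["rx_over_dmax"]], 2),
    rx_over_dmax_max = round_half_up(cur[["rx_over_dmax_max"]] *
                                       rat[["rx_over_dmax"]], 2))
  data.frame(metric = names(prop),
             current = unname(cur[names(prop)]),
             proposed = unname(prop),
             stringsAsFactors = FALSE)
}

#' Scaled volume-specific guideline table
#'
#' Each current CI / D2cm / R50 threshold times its metric's cohort-mean
#' ratio, under per-column rounding rules matched to how such limits are
#' conventionally printed: D2cm to the nearest integer percent, R50
#' truncated at 2 decimals, CI rounded to 2 decimals. By default only rows
#' in the volume range supported by the cohort (13.2-50 cc) are emitted;
#' `full_range = TRUE` derives all rows with a warning.
#'
#' @param current a [rtog_guidelines()] object.
#' @param r a [scaling_factors()] object with `ci`, `d2cm_prime` and
#'   `r50_prime` ratios.
#' @param rounding named list of per-column rounding functions; the default
#'   encodes the rules above.
#' @param volume_range_cc volume range of rows to emit.
#' @param full_range derive all table rows regardless of `volume_range_cc`.
#' @return Data frame with current and proposed variation (none/minor
#'   boundary) and deviation (minor/major boundary) columns per PTV volume.
#' @export
scale_volume_table <- function(current, r,
                               rounding = list(
                                 ci = function(x) round_half_up(x, 2),
                                 d2cm = function(x) round_half_up(x, 0),
                                 r50 = function(x) trunc_decimals(x, 2)),
                               volume_range_cc = c(13.2, 50),
                               full_range = FALSE) {
  stopifnot(inherits(current, "guideline_set"), inherits(r, "scaling_factors"))
  need <- c("ci", "d2cm_prime", "r50_prime")
  miss <- setdiff(need, names(r$ratios))
  if (length(miss) > 0)
    stop("incomplete derivation: missing ratios for ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(c("ci", "d2cm", "r50") %in% names(rounding)) ||
      !all(vapply(rounding, is.function, logical(1))))
    stop("configuration error: `rounding` must supply functions for ci, d2cm, r50",
         call. = FALSE)
  rows <- current$rows
  if (full_range) {
    warning("deriving guideline rows beyond the 13.2-50 cc range supported ",
            "by the cohort", call. = FALSE)
  } else {
    rows <- rows[rows$ptv_cc >= volume_range_cc[1] &
                   rows$ptv_cc <= volume_range_cc[2], ]
  }
  rat <- r$ratios
  data.frame(
    ptv_cc = rows$ptv_cc,
    ci_variation_current = rows$ci_none,
    ci_deviation_current = rows$ci_minor_upper,
    ci_variation_proposed = rounding$ci(rows$ci_none * rat[["ci"]]),
    ci_deviation_proposed = rounding$ci(rows$ci_minor_upper * rat[["ci"]]),
    d2cm_variation_current = rows$d2cm_none,
    d2cm_deviation_current = rows$d2cm_minor_upper,
    d2cm_variation_proposed = rounding$d2cm(rows$d2cm_none *
                                              rat[["d2cm_prime"]]),
    d2cm_deviation_proposed = rounding$d2cm(rows$d2cm_minor_upper *
                                              rat[["d2cm_prime"]]),
    r50_variation_current = rows$r50_none,
    r50_deviation_current = rows$r50_minor_upper,
    r50_variation_proposed = rounding$r50(rows$r50_none *
                                            rat[["r50_prime"]]),
    r50_deviation_proposed = rounding$r50(rows$r50_minor_upper *
                                            rat[["r50_prime"]]))
}

#' Prescription dose under a proposed coverage recommendation
#'
#' The prescription scaled by the proposed D95 percentage, rounded to
#' 0.01 Gy — the dose reduction that preserves delivered coverage when the
#' coverage recommendation drops below 100%.
#'
#' @param rx_gy current prescription, Gy (> 0).
#' @param d95_proposed_pct proposed D95 as percent of Rx, in (0, 100].
#' @return Scaled prescription, Gy.
#' @export
scaled_prescription <- function(rx_gy, d95_proposed_pct) {
  stopifnot(rx_gy > 0, d95_proposed_pct > 0, d95_proposed_pct <= 100)
  round_half_up(rx_gy * d95_proposed_pct / 100, 2)
}

#' Derive an algorithm-adapted guideline set
#'
#' Convenience wrapper: computes cohort-mean ratios (from a paired cohort
#' table, or accepts precomputed [scaling_factors()]) and emits both the
#' volume-independent limits and the volume-specific threshold table.
#'
#' @param x a paired cohort table or a [scaling_factors()] object.
#' @param current the current [rtog_guidelines()].
#' @param ... passed to [scale_volume_table()].
#' @return Object of class `proposed_guidelines` with elements
#'   `volume_independent`, `volume_table`, `factors`.
#' @export
derive_guidelines <- function(x, current = rtog_guidelines(), ...) {
  r <- if (inherits(x, "scaling_factors")) x else cohort_ratios(x)
  structure(list(
    volume_independent = scale_volume_independent(current, r),
    volume_table = scale_volume_table(current, r, ...),
    factors = r), class = "proposed_guidelines")
}

#' @export
print.scaling_factors <- function(x, ...) {
  cat(sprintf("<scaling_factors> recalculated/plan cohort-mean ratios (n = %s)\n",
              x$n))
  print(round(rbind(plan = x$plan_means, recalculated = x$recalc_means,
                    ratio = x$ratios), 4))
  invisible(x)
}

#' @export
print.proposed_guidelines <- function(x, ...) {
  cat("proposed volume-independent limits:\n")
  print(x$volume_independent, row.names = FALSE)
  cat("proposed volume-specific thresholds:\n")
  print(x$volume_table, row.names = FALSE)
  invisible(x)
}
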