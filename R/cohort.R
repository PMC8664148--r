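#' Paired two-sided t-test (closed form)
#'
#' Classical paired t on the within-pair differences with `df = n - 1` and a
#' two-sided p-value from the t distribution. Zero-variance differences are
#' flagged as degenerate rather than reported with an unstable p-value.
#'
#' @param x,y paired numeric vectors of equal length `>= 2`, aligned by
#'   patient.
#' @return List with `t`, `df`, `p`, `mean_diff`, `n`, and `degenerate`
#'   (TRUE when the differences have zero variance).
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y))
    stop("pairing error: series have different lengths", call. = FALSE)
  n <- length(x)
  stopifnot(n >= 2)
  d <- y - x
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    return(list(t = NA_real_, df = n - 1L, p = NA_real_,
                mean_diff = mean(d), n = n, degenerate = TRUE))
  }
  tval <- mean(d) / (sd_d / sqrt(n))
  list(t = tval, df = n - 1L,
       p = 2 * stats::pt(-abs(tval), df = n - 1),
       mean_diff = mean(d), n = n, degenerate = FALSE)
}

#' Relative difference of a metric between arms
#'
#' `(m_recalc - m_plan) / m_plan`, the quantity plotted against PTV volume
#' when assessing size dependence of the algorithm difference.
#'
#' @param m_plan baseline (plan-arm) value, nonzero.
#' @param m_recalc comparison (recalculated-arm) value.
#' @return Dimensionless relative difference.
#' @export
relative_difference <- function(m_plan, m_recalc) {
  if (any(m_plan == 0))
    stop("undefined ratio: baseline metric value is zero", call. = FALSE)
  (m_recalc - m_plan) / m_plan
}

#' Deviation counts per metric and arm
#'
#' Classifies every cohort row against the guidelines and tabulates minor /
#' major deviation counts (and the pass/fail deviations of the
#' volume-independent metrics) per arm, overall and within the island
#' subgroup, with "minor, major" totals.
#'
#' @param cohort a cohort metrics table.
#' @param set a [rtog_guidelines()] object.
#' @return Object of class `deviation_counts`: data frame with one row per
#'   (arm, subgroup), counts per metric and class, and totals.
#' @export
deviation_count_table <- function(cohort, set = rtog_guidelines()) {
  stopifnot(is.data.frame(cohort))
  reports <- lapply(seq_len(nrow(cohort)),
                    function(i) classify_plan(cohort[i, ], set))
  banded_metrics <- c("ci", "r50", "d2cm")
  pf_metrics <- c("v100", "v90", "v105", "rx_over_dmax")
  groups <- list(all = rep(TRUE, nrow(cohort)))
  if ("island" %in% names(cohort) && any(cohort$island %in% TRUE))
    groups$island <- cohort$island %in% TRUE
  out <- list()
  for (gname in names(groups)) {
    g <- groups[[gname]]
    for (arm in unique(cohort$arm)) {
      idx <- which(g & cohort$arm == arm)
      if (length(idx) == 0) next
      row <- list(subgroup = gname, arm = arm, n = length(idx))
      total_minor <- 0L; total_major <- 0L
      for (m in banded_metrics) {
        cls <- vapply(reports[idx], function(r) r$banded[[m]], character(1))
        row[[paste0(m, "_minor")]] <- sum(cls == "minor", na.rm = TRUE)
        row[[paste0(m, "_major")]] <- sum(cls == "major", na.rm = TRUE)
        total_minor <- total_minor + row[[paste0(m, "_minor")]]
        total_major <- total_major + row[[paste0(m, "_major")]]
      }
      for (m in pf_metrics) {
        cls <- vapply(reports[idx], function(r) r$pass_fail[[m]], character(1))
        row[[paste0(m, "_deviation")]] <- sum(cls == "deviation", na.rm = TRUE)
      }
      row$total_minor <- total_minor
      row$total_major <- total_major
      out[[length(out) + 1L]] <- as.data.frame(row, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("deviation_counts", "data.frame")
  res
}

#' Stratify a cohort by PTV volume and test the size effect
#'
#' Splits patients at a PTV-volume cutoff (default 20 cc) into small and
#' large strata and, for each metric, compares the plan-to-recalculated
#' relative differences between the strata with an unpaired two-sided
#' t-test.
#'
#' @param cohort a paired cohort metrics table.
#' @param cutoff_cc volume cutoff, cc.
#' @param metrics metric columns to test.
#' @return List with the two subcohort id sets, per-metric tests (data
#'   frame), and a `stratum_empty` flag (tests skipped when a stratum is
#'   empty).
#' @export
stratify_by_volume <- function(cohort, cutoff_cc = 20,
                               metrics = c("d95_pct", "v100_pct", "ci",
                                           "d2cm_pct", "r50", "mu_total")) {
  stopifnot(is.data.frame(cohort))
  a <- cohort[cohort$arm == "plan", ]
  b <- cohort[cohort$arm == "recalculated", ]
  b <- b[match(a$patient_id, b$patient_id), ]
  small <- a$ptv_cc < cutoff_cc
  res <- list(cutoff_cc = cutoff_cc,
              small_ids = a$patient_id[small],
              large_ids = a$patient_id[!small],
              stratum_empty = !any(small) || all(small))
  if (res$stratum_empty) {
    res$tests <- NULL
    return(res)
  }
  tests <- lapply(metrics, function(m) {
    rd <- relative_difference(a[[m]], b[[m]])
    tt <- stats::t.test(rd[small], rd[!small], var.equal = FALSE)
    data.frame(metric = m,
               mean_rd_small = mean(rd[small]),
               mean_rd_large = mean(rd[!small]),
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  res$tests <- do.call(rbind, tests)
  res
}

#' Paired arm-vs-arm comparison summary for a cohort
#'
#' Cohort means per arm, mean paired differences, and two-sided paired
#' t-tests for every metric, between a reference arm and a comparison arm.
#'
#' @param cohort a cohort metrics table with paired arms.
#' @param arms length-2 character: reference and comparison arm.
#' @param alpha significance level for the flag column.
#' @return Object of class `cohort_comparison` (a data frame).
#' @export
compare_cohort <- function(cohort, arms = c("plan", "recalculated"),
                           alpha = 0.05) {
  stopifnot(is.data.frame(cohort), all(arms %in% cohort$arm))
  a <- cohort[cohort$arm == arms[1], ]
  b <- cohort[cohort$arm == arms[2], ]
  b <- b[match(a$patient_id, b$patient_id), ]
  if (any(is.na(b$patient_id)))
    stop("pairing error: patients missing the comparison arm", call. = FALSE)
  metrics <- intersect(c("d95_pct", "v100_pct", "dmin_pct", "v90_pct",
                         "rx_over_dmax", "v105_pct_of_ptv", "ci",
                         "d2cm_prime", "r50_prime", "mu_total"),
                       names(cohort))
  rows <- lapply(metrics, function(m) {
    tt <- paired_t(a[[m]], b[[m]])
    data.frame(metric = m,
               mean_ref = mean(a[[m]]), mean_cmp = mean(b[[m]]),
               mean_diff = tt$mean_diff, t = tt$t, df = tt$df, p = tt$p,
               n = tt$n,
               significant = !is.na(tt$p) && tt$p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "arms") <- arms
  class(out) <- c("cohort_comparison", "data.frame")
  out
}

#' @export
print.cohort_comparison <- function(x, ...) {
  arms <- attr(x, "arms")
  cat(sprintf("cohort comparison: %s vs %s (paired two-sided t, n = %d)\n",
              arms[1], arms[2], x$n[1]))
  y <- as.data.frame(x)
  y$p <- ifelse(is.na(y$p), "degenerate",
                ifelse(y$p < 0.01, "<0.01", sprintf("%.3f", y$p)))
  y$t <- round(y$t, 3)
  y[c("mean_ref", "mean_cmp", "mean_diff")] <-
    round(y[c("mean_ref", "mean_cmp", "mean_diff")], 4)
  print(y[c("metric", "mean_ref", "mean_cmp", "mean_diff", "t", "p",
            "significant")], row.names = FALSE)
  invisible(x)
}
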