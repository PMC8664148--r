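cohort_schema <- c("patient_id", "arm", "algorithm", "ptv_cc", "d95_pct",
                   "v100_pct", "v90_pct", "dmin_pct", "dmax_pct",
                   "rx_over_dmax", "v105_pct_of_ptv", "ci", "r50",
                   "d2cm_pct", "d2cm_prime", "r50_prime", "mu_total",
                   "island")

valid_arms <- c("plan", "recalculated", "renormalized")

#' Read / write a cohort metrics table as CSV
#'
#' The cohort table has one row per (patient, arm) with the full metric
#' vector. The schema is enforced on read: all columns present, arm labels
#' in the known vocabulary, no duplicate (patient, arm) pairs.
#'
#' @param path CSV path.
#' @return `read_cohort_csv`: the cohort data frame.
#' @export
read_cohort_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(cohort_schema, names(tab))
  if (length(miss) > 0)
    stop("schema error: missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(tab$arm), valid_arms)
  if (length(bad) > 0)
    stop("schema error: unknown arm label(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  key <- paste(tab$patient_id, tab$arm)
  if (anyDuplicated(key))
    stop("duplicate (patient, arm) rows: ",
         paste(unique(key[duplicated(key)]), collapse = ", "),
         call. = FALSE)
  tab$island <- as.logical(tab$island)
  tab[cohort_schema]
}

#' @rdname read_cohort_csv
#' @param table cohort data frame.
#' @return `write_cohort_csv`: `path`, invisibly.
#' @export
write_cohort_csv <- function(table, path) {
  miss <- setdiff(cohort_schema, names(table))
  if (length(miss) > 0)
    stop("schema error: missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  utils::write.csv(table[cohort_schema], path, row.names = FALSE)
  invisible(path)
}
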