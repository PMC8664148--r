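#' Read a plan from a JSON manifest
#'
#' The manifest names the dose and mask NRRD files (paths relative to the
#' manifest's directory) and carries the plan bookkeeping: `rx_gy`,
#' `n_fractions`, `mu_total`, `algorithm`, `arm`, `patient_id`.
#'
#' @param path manifest path.
#' @return An [sbrt_plan()].
#' @export
read_plan <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("dose", "masks", "rx_gy", "mu_total")
  miss <- setdiff(need, names(m))
  if (length(miss) > 0)
    stop("manifest missing fields: ", paste(miss, collapse = ", "),
         call. = FALSE)
  dir <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(dir, p)
  dose <- read_nrrd(resolve(m$dose), as = "dose")
  masks <- lapply(seq_along(m$masks), function(i)
    read_nrrd(resolve(unlist(m$masks[i])), as = "mask",
              label = names(m$masks)[i]))
  names(masks) <- names(m$masks)
  sbrt_plan(dose, masks, rx_gy = m$rx_gy,
            n_fractions = m$n_fractions %||% 5,
            mu_total = m$mu_total,
            algorithm = m$algorithm %||% "AAA",
            arm = m$arm %||% "plan",
            patient_id = m$patient_id %||% NA_character_)
}

#' Write a plan as NRRD files plus a JSON manifest
#'
#' @param plan an [sbrt_plan()].
#' @param dir output directory (created if needed).
#' @param name basename for the manifest and grid files.
#' @return Path of the manifest, invisibly.
#' @export
write_plan <- function(plan, dir, name = plan$patient_id %||% "plan") {
  if (is.na(name)) name <- "plan"
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dose_file <- paste0(name, "_dose.nrrd")
  write_nrrd(plan$dose, file.path(dir, dose_file))
  mask_files <- list()
  for (nm in names(plan$masks)) {
    f <- paste0(name, "_mask_", nm, ".nrrd")
    write_nrrd(plan$masks[[nm]], file.path(dir, f))
    mask_files[[nm]] <- f
  }
  manifest <- list(dose = dose_file, masks = mask_files,
                   rx_gy = plan$rx_gy, n_fractions = plan$n_fractions,
                   mu_total = plan$mu_total, algorithm = plan$algorithm,
                   arm = plan$arm, patient_id = plan$patient_id)
  mpath <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}

#' Serialize a guideline set to JSON
#'
#' @param set a [rtog_guidelines()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_guidelines_json <- function(set, path) {
  stopifnot(inherits(set, "guideline_set"))
  jsonlite::write_json(unclass(set), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Read a guideline set from JSON
#'
#' @param path JSON file written by [write_guidelines_json()].
#' @return A [rtog_guidelines()] object.
#' @export
read_guidelines_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rtog_guidelines(rows = as.data.frame(x$rows),
                  v100_target_pct = x$v100_target_pct,
                  v90_min_pct = x$v90_min_pct,
                  v105_max_pct = x$v105_max_pct,
                  rx_over_dmax_range = x$rx_over_dmax_range,
                  d95_target_pct = x$d95_target_pct,
                  chestwall_v30_max_cc = x$chestwall_v30_max_cc,
                  lung_v20_max_pct = x$lung_v20_max_pct)
}
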