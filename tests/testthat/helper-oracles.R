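# Independent brute-force oracles and small fixture builders. The oracles
# deliberately use naive sort/scan/enumeration so they share no code with
# the implementation they check.

uniform_grid <- function(dose_gy, dim = c(4, 4, 4), spacing = c(10, 10, 10)) {
  dose_grid(array(dose_gy, dim), spacing)
}

full_mask <- function(grid, label = "PTV") {
  structure_mask(array(TRUE, dim(grid$values)), grid$spacing, grid$origin,
                 label = label)
}

random_grid <- function(dim, spacing = c(2, 2, 2), max_gy = 80) {
  dose_grid(array(stats::runif(prod(dim), 0, max_gy), dim), spacing)
}

random_mask <- function(dim, spacing = c(2, 2, 2), p = 0.3,
                        label = "PTV") {
  v <- array(stats::runif(prod(dim)) < p, dim)
  if (!any(v)) v[sample(length(v), 1)] <- TRUE
  structure_mask(v, spacing, label = label)
}

# largest dose d such that fraction of voxels with dose >= d is >= x/100
brute_dose_at_volume <- function(doses, x) {
  cand <- sort(unique(doses), decreasing = TRUE)
  n <- length(doses)
  best <- NA_real_
  for (d in cand) {
    if (sum(doses >= d) / n >= x / 100) { best <- d; break }
  }
  best
}

brute_volume_at_dose <- function(doses, d) 100 * mean(doses >= d)

# max dose d with volume strictly below d at most cold_cc: enumerate over
# exclusion prefixes of the ascending-sorted doses
brute_near_min <- function(doses, voxel_cc, cold_cc) {
  s <- sort(doses)
  best <- s[1]
  for (k in seq_along(s)) {
    d <- s[k]
    if (sum(s < d) * voxel_cc <= cold_cc) best <- max(best, d)
  }
  best
}

brute_isodose_cc <- function(doses, voxel_cc, level)
  sum(doses >= level) * voxel_cc

# all-pairs nearest distance from every voxel centre to the mask
brute_distance_field <- function(mask) {
  d <- dim(mask$voxels)
  sp <- mask$spacing
  idx <- which(mask$voxels, arr.ind = TRUE)
  pts <- sweep(idx - 1, 2, sp, "*")
  out <- array(NA_real_, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    p <- c((i - 1) * sp[1], (j - 1) * sp[2], (k - 1) * sp[3])
    out[i, j, k] <- sqrt(min(colSums((t(pts) - p)^2)))
  }
  out
}

# reference cohort means from the published comparison (plan vs
# recalculated arms), used to drive the derivation pipeline
published_plan_means <- c(
  d95_pct = 100.00, v100_pct = 95.00, v90_pct = 100.0, rx_over_dmax = 0.830,
  v105_pct_of_ptv = 6.3, ci = 1.15, d2cm_prime = 1.004, r50_prime = 0.899)

published_recalc_means <- c(
  d95_pct = 98.21, v100_pct = 91.40, v90_pct = 99.8, rx_over_dmax = 0.823,
  v105_pct_of_ptv = 5.4, ci = 1.07, d2cm_prime = 0.988, r50_prime = 0.892)

# minimal complete metrics list for classification tests
metrics_stub <- function(ptv_cc = 10, ci = 1.0, r50 = 4.0, d2cm_pct = 45,
                         v100_pct = 95, v90_pct = 99.5,
                         v105_pct_of_ptv = 5, rx_over_dmax = 0.8) {
  list(ptv_cc = ptv_cc, ci = ci, r50 = r50, d2cm_pct = d2cm_pct,
       v100_pct = v100_pct, v90_pct = v90_pct,
       v105_pct_of_ptv = v105_pct_of_ptv, rx_over_dmax = rx_over_dmax)
}

# tiny-but-complete synthetic plan: fast to build, exercises every metric
tiny_config <- function(seed = 7, n = 2) {
  cohort_config(n_patients = n, island_fraction = 0.5,
                ptv_volume_range_cc = c(7.58, 25),
                grid_dim = c(40, 36, 36), seed = seed)
}
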