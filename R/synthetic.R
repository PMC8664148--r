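#' Algorithm-shift parameters for the synthetic cohort
#'
#' Phenomenological description of what happens when a convolution-algorithm
#' lung SBRT plan is recalculated with a linear Boltzmann transport engine:
#' a per-patient global dose-per-MU reduction concentrated near the target
#' (lost lateral build-up in lung), a deepened cold rim, a boosted interior
#' hotspot, and a slight tightening of the out-of-field penumbra. The shift
#' operates on metric-level dose structure, not on particle transport.
#'
#' Defaults are calibrated once so that a 30-patient cohort reproduces the
#' reference cohort means (overall D95 ratio 0.9821, island 0.9703, Rx/Dmax
#' ratio 0.823/0.830); the calibration script ships in `tools/`.
#'
#' @param d95_ratio_mean mean recalculated/plan D95 ratio for non-island
#'   targets.
#' @param d95_ratio_mean_island mean ratio for island-type targets (lower:
#'   no chest-wall build-up).
#' @param d95_ratio_sd per-patient standard deviation of the ratio.
#' @param dmax_boost_mean fractional boost of the interior hotspot.
#' @param cold_rim_deepening extra fractional reduction of doses below the
#'   prescription level (deepens the PTV cold rim).
#' @param penumbra_tightening fractional reduction of out-of-field dose far
#'   from the target.
#' @param buildup_range_mm distance scale (mm) over which the global
#'   reduction fades with distance from the PTV.
#' @param anchor_correction deterministic divisor keeping the realized D95
#'   ratio equal to the drawn ratio despite the rim/boost gates (set by the
#'   calibration script).
#' @return Object of class `shift_params`.
#' @export
shift_params <- function(d95_ratio_mean = 0.9911,
                         d95_ratio_mean_island = 0.9703,
                         d95_ratio_sd = 0.020,
                         dmax_boost_mean = 0.029,
                         cold_rim_deepening = 0.010,
                         penumbra_tightening = 0.002,
                         buildup_range_mm = 5,
                         anchor_correction = NULL) {
  stopifnot(d95_ratio_mean > 0.8, d95_ratio_mean < 1.2,
            d95_ratio_mean_island > 0.8, d95_ratio_mean_island < 1.2,
            d95_ratio_sd >= 0)
  p <- list(d95_ratio_mean = d95_ratio_mean,
            d95_ratio_mean_island = d95_ratio_mean_island,
            d95_ratio_sd = d95_ratio_sd,
            dmax_boost_mean = dmax_boost_mean,
            cold_rim_deepening = cold_rim_deepening,
            penumbra_tightening = penumbra_tightening,
            buildup_range_mm = buildup_range_mm)
  p$anchor_correction <- anchor_correction %||% shift_anchor_gain(p)
  structure(p, class = "shift_params")
}

# dose-level gates of the algorithm shift, on the dose/Rx scale
shift_boost_gate <- function(rel) stats::plogis((rel - 1.10) / 0.03)
shift_rim_gate <- function(rel) stats::plogis(-(rel - 0.96) / 0.02)

# combined gate response at the prescription level (rel = 1); dividing the
# drawn ratio by this keeps the realized D95 ratio on target
shift_anchor_gain <- function(p) {
  (1 + p$dmax_boost_mean * shift_boost_gate(1)) *
    (1 - p$cold_rim_deepening * shift_rim_gate(1))
}

#' Synthetic cohort configuration
#'
#' Study conditions for the paired-plan generator: 30 patients of whom 13
#' have island-type targets, PTV volumes spanning 7.58-74.06 cc
#' (log-normal, mean near 21 cc), prescription 60 Gy in 5 fractions, and a
#' 2.5 mm isotropic dose grid.
#'
#' @param n_patients number of patients.
#' @param island_fraction proportion with island-type targets.
#' @param ptv_volume_range_cc truncation range of the PTV volume draw, cc.
#' @param ptv_volume_meanlog,ptv_volume_sdlog log-normal volume parameters.
#' @param grid_dim,spacing_mm dose grid shape and voxel spacing.
#' @param rx_gy,n_fractions prescription.
#' @param seed integer seed; all randomness derives from it.
#' @param shift a [shift_params()] object.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 30,
                          island_fraction = 13 / 30,
                          ptv_volume_range_cc = c(7.58, 74.06),
                          ptv_volume_meanlog = log(19),
                          ptv_volume_sdlog = 0.42,
                          grid_dim = c(56, 48, 48),
                          spacing_mm = c(2.5, 2.5, 2.5),
                          rx_gy = 60,
                          n_fractions = 5,
                          seed = 1,
                          shift = shift_params()) {
  stopifnot(n_patients >= 1, island_fraction >= 0, island_fraction <= 1,
            length(grid_dim) == 3, all(grid_dim >= 16),
            all(spacing_mm > 0), rx_gy > 0)
  structure(list(n_patients = as.integer(n_patients),
                 island_fraction = island_fraction,
                 ptv_volume_range_cc = ptv_volume_range_cc,
                 ptv_volume_meanlog = ptv_volume_meanlog,
                 ptv_volume_sdlog = ptv_volume_sdlog,
                 grid_dim = as.integer(grid_dim),
                 spacing_mm = spacing_mm,
                 rx_gy = rx_gy, n_fractions = n_fractions,
                 seed = as.integer(seed), shift = shift,
                 chestwall_mm = 10,
                 interior_grad_exp = 3.7,
                 falloff_shape = 1),
            class = "cohort_config")
}

# deterministic per-patient sub-seed (kept well below 2^31)
patient_seed <- function(config, i, salt = 0L) {
  (abs(config$seed) %% 1000000L) * 1000L + 104729L %% 1000L + i * 131L +
    salt * 7919L
}

# which patients are island-type, as a deterministic function of the seed
island_assignment <- function(config) {
  k <- round(config$n_patients * config$island_fraction)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(patient_seed(config, 0L, salt = 5L))
  idx <- sample(config$n_patients, k)
  seq_len(config$n_patients) %in% idx
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

# voxel-centre coordinates along each axis, mm
axis_coords <- function(config) {
  lapply(1:3, function(a)
    (seq_len(config$grid_dim[a]) - 1) * config$spacing_mm[a])
}

# squared distance of every voxel centre from a point, mm^2
dist2_from_point <- function(coords, p) {
  dx2 <- (coords[[1]] - p[1])^2
  dy2 <- (coords[[2]] - p[2])^2
  dz2 <- (coords[[3]] - p[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+")
}

# offset of the dose centre from the PTV centre such that the dose sphere
# (radius rho_a) covers `coverage` of the PTV sphere (radius rs)
solve_offset <- function(rs, rho_a, coverage = 0.95) {
  v_ptv <- 4 / 3 * pi * rs^3
  lens <- function(d) {
    if (d <= rho_a - rs) return(v_ptv)
    if (d >= rho_a + rs) return(0)
    pi * (rho_a + rs - d)^2 *
      (d^2 + 2 * d * (rho_a + rs) - 3 * (rho_a - rs)^2) / (12 * d)
  }
  target <- coverage * v_ptv
  lo <- max(rho_a - rs, 1e-6) + 1e-9
  if (lens(lo) < target) return(lo)
  stats::uniroot(function(d) lens(d) - target, c(lo, rho_a + rs - 1e-6),
                 tol = 1e-8)$root
}

#' Generate one synthetic baseline plan
#'
#' Builds a spherical PTV (placed against a chest-wall slab for non-island
#' patients, well away from it for island patients) and a conformal dose
#' distribution around it: a heterogeneous interior rising from the
#' prescription at the target boundary to a controlled hotspot, the
#' prescription isodose slightly larger than and offset from the PTV (so
#' conformality exceeds 1 while coverage is 95%), an exponential-type
#' falloff tuned per patient to the drawn R50, and a small near-target hot
#' lobe supplying the V105 volume. The dose is normalized so D95 equals the
#' prescription exactly.
#'
#' @param config a [cohort_config()].
#' @param patient_index patient number in `1:n_patients`; the same
#'   `(seed, index)` pair always yields the identical plan.
#' @return An [sbrt_plan()] with arm `"plan"` and algorithm `"AAA"`.
#' @export
generate_phantom_plan <- function(config, patient_index) {
  stopifnot(inherits(config, "cohort_config"),
            patient_index >= 1, patient_index <= config$n_patients)
  i <- as.integer(patient_index)
  island <- island_assignment(config)[i]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(patient_seed(config, i, salt = 1L))

  vr <- config$ptv_volume_range_cc
  vol_cc <- exp(rnorm_trunc(1, config$ptv_volume_meanlog,
                            config$ptv_volume_sdlog, log(vr[1]), log(vr[2])))
  rs <- (3 * vol_cc * 1000 / (4 * pi))^(1 / 3)  # mm

  set_ <- rtog_guidelines()
  thr <- interpolate_thresholds(set_, vol_cc)
  ci_target <- rnorm_trunc(1, 1.15, 0.05, 1.03, 1.32)
  r50p_target <- rnorm_trunc(1, 0.899, 0.09, 0.68, 1.18)
  r50_target <- r50p_target * thr$r50_none
  rx_over_dmax <- rnorm_trunc(1, 0.830, 0.030, 0.62, 0.88)
  hot_peak <- 1 / rx_over_dmax

  rho_a <- rs * ci_target^(1 / 3)             # Rx isodose radius
  rho_50 <- max(rs * r50_target^(1 / 3), rho_a + 2)
  h <- rho_50 - rho_a                         # falloff half-distance

  # geometry: chest-wall slab at low x; PTV centre
  ext <- config$grid_dim * config$spacing_mm
  slab <- config$chestwall_mm
  gap <- if (island) stats::runif(1, 14, 28) else stats::runif(1, 0, 4)
  centre <- c(slab + gap + rs, ext[2] / 2, ext[3] / 2)
  if (centre[1] + rho_a + 5 > ext[1])
    stop("geometry error: PTV does not fit in the grid", call. = FALSE)

  # dose-centre offset giving 95% coverage at the drawn conformality
  o_mag <- solve_offset(rs, rho_a, 0.95)
  o_dir <- stats::rnorm(3)
  o_dir <- o_dir / sqrt(sum(o_dir^2))
  dose_centre <- centre + o_mag * o_dir

  coords <- axis_coords(config)
  rho <- sqrt(dist2_from_point(coords, dose_centre))
  kappa <- config$interior_grad_exp
  beta <- config$falloff_shape
  rel <- ifelse(rho <= rho_a,
                1 + (hot_peak - 1) * (1 - (rho / rho_a)^kappa),
                2^(-((rho - rho_a) / h)^beta))

  # near-target hot lobe (outside the PTV) for a realistic V105
  bump_amp <- rnorm_trunc(1, 0.085, 0.04, 0, 0.25)
  bump_dir <- stats::rnorm(3)
  bump_dir <- bump_dir / sqrt(sum(bump_dir^2))
  bump_centre <- centre + (rs + 2) * bump_dir
  rel <- rel + bump_amp * exp(-dist2_from_point(coords, bump_centre) /
                                (2 * 3.5^2))

  ptv_vox <- dist2_from_point(coords, centre) <= rs^2
  cw_vox <- outer(outer(coords[[1]] < slab, rep(TRUE, config$grid_dim[2]),
                        "&"), rep(TRUE, config$grid_dim[3]), "&")
  masks <- list(
    PTV = structure_mask(ptv_vox, config$spacing_mm, label = "PTV"),
    chestwall = structure_mask(cw_vox, config$spacing_mm,
                               label = "chestwall"),
    body = structure_mask(array(TRUE, config$grid_dim), config$spacing_mm,
                          label = "body"))

  dose_gy <- config$rx_gy * rel
  grid <- dose_grid(dose_gy, config$spacing_mm)
  d95 <- dose_at_volume_pct(dose_sample(grid, masks$PTV), 95)
  grid$values <- grid$values * (config$rx_gy / d95)

  mu <- rnorm_trunc(1, if (island) 2301 else 1973, 250, 1200, 3500)
  sbrt_plan(grid, masks, rx_gy = config$rx_gy,
            n_fractions = config$n_fractions, mu_total = mu,
            algorithm = "AAA", arm = "plan",
            patient_id = sprintf("P%02d", i))
}

#' Apply the algorithm shift to a baseline plan
#'
#' Emulates recalculating the plan with the Boltzmann-transport engine at
#' the original monitor units: the dose is multiplied by a per-patient
#' factor (drawn around the island or non-island D95 ratio) that fades with
#' distance from the PTV, doses below the prescription are deepened
#' slightly (cold rim), the hotspot is boosted, and far-field dose is
#' tightened. MU are unchanged.
#'
#' @param plan an [sbrt_plan()] with arm `"plan"`.
#' @param shift a [shift_params()] object.
#' @param island logical island flag; if `NULL`, classified from the plan's
#'   chest-wall mask.
#' @param seed integer seed for the per-patient ratio draw.
#' @param dist optional precomputed PTV [distance_from_mask()] field.
#' @return The recalculated plan (arm `"recalculated"`, algorithm `"AXB"`).
#' @export
apply_algorithm_shift <- function(plan, shift = shift_params(),
                                  island = NULL, seed = 1, dist = NULL) {
  stopifnot(inherits(plan, "sbrt_plan"), inherits(shift, "shift_params"))
  if (plan$arm != "plan")
    stop("arm error: the shift applies to an original 'plan'-arm plan",
         call. = FALSE)
  if (is.null(island))
    island <- classify_island(plan$masks$PTV, plan$masks$chestwall)
  if (is.na(island)) island <- FALSE
  if (is.null(dist)) dist <- distance_from_mask(plan$masks$PTV)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  mu_ratio <- if (island) shift$d95_ratio_mean_island else shift$d95_ratio_mean
  t_p <- rnorm_trunc(1, mu_ratio, shift$d95_ratio_sd, 0.90, 1.06)

  f_base <- t_p / shift$anchor_correction
  rel <- plan$dose$values / plan$rx_gy
  dout <- dist$distances
  fade <- exp(-(dout / shift$buildup_range_mm)^2)
  factor <- (1 - (1 - f_base) * fade) *
    (1 - shift$penumbra_tightening * (1 - fade)) *
    (1 + shift$dmax_boost_mean * shift_boost_gate(rel)) *
    (1 - shift$cold_rim_deepening * shift_rim_gate(rel))

  new_plan <- plan
  new_plan$dose$values <- plan$dose$values * factor
  new_plan$algorithm <- "AXB"
  new_plan$arm <- "recalculated"
  new_plan
}

#' Generate a paired synthetic cohort and its metrics table
#'
#' For each patient: a baseline plan, its recalculated counterpart (original
#' MU), and the renormalized plan (coverage restored, MU scaled); the full
#' metric vector is computed for every arm. Deterministic for a given seed.
#'
#' @param config a [cohort_config()].
#' @param keep_plans return the plan objects as well (memory-heavy; off by
#'   default).
#' @param arms which arms to generate.
#' @return A cohort metrics table (data frame, one row per patient-arm, the
#'   standard cohort schema); with `keep_plans = TRUE`, a list
#'   `(table, plans)`.
#' @export
generate_cohort <- function(config = cohort_config(), keep_plans = FALSE,
                            arms = c("plan", "recalculated", "renormalized")) {
  stopifnot(inherits(config, "cohort_config"))
  set_ <- rtog_guidelines()
  rows <- list()
  plans <- list()
  cw_dist <- NULL
  for (i in seq_len(config$n_patients)) {
    p <- generate_phantom_plan(config, i)
    if (is.null(cw_dist)) cw_dist <- distance_from_mask(p$masks$chestwall)
    dist <- distance_from_mask(p$masks$PTV)
    island <- classify_island(p$masks$PTV, NULL, dist = cw_dist)
    arm_plans <- list()
    if ("plan" %in% arms) arm_plans$plan <- p
    if (any(c("recalculated", "renormalized") %in% arms)) {
      rec <- apply_algorithm_shift(p, config$shift, island = island,
                                   seed = patient_seed(config, i, salt = 2L),
                                   dist = dist)
      if ("recalculated" %in% arms) arm_plans$recalculated <- rec
      if ("renormalized" %in% arms)
        arm_plans$renormalized <- renormalize(rec)$plan
    }
    for (pl in arm_plans) {
      m <- plan_metrics(pl, set_, dist = dist, chestwall_dist = cw_dist)
      rows[[length(rows) + 1L]] <- m
    }
    if (keep_plans) plans[[i]] <- arm_plans
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  class(tab) <- "data.frame"
  if (keep_plans) list(table = tab, plans = plans) else tab
}

#' @export
print.shift_params <- function(x, ...) {
  cat(sprintf("<shift_params> D95 ratio %.4f (island %.4f) sd %.3f | boost %.3f | rim %.3f | penumbra %.3f | range %.0f mm\n",
              x$d95_ratio_mean, x$d95_ratio_mean_island, x$d95_ratio_sd,
              x$dmax_boost_mean, x$cold_rim_deepening,
              x$penumbra_tightening, x$buildup_range_mm))
  invisible(x)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config> n = %d (island fraction %.3f), PTV %.2f-%.2f cc, Rx %.0f Gy/%d fx, grid %s @ %s mm, seed %d\n",
              x$n_patients, x$island_fraction, x$ptv_volume_range_cc[1],
              x$ptv_volume_range_cc[2], x$rx_gy, x$n_fractions,
              paste(x$grid_dim, collapse = "x"),
              paste(x$spacing_mm, collapse = "x"), x$seed))
  print(x$shift)
  invisible(x)
}
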