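#' Dose sample of a structure
#'
#' Extracts the multiset of per-voxel doses inside a structure, the primitive
#' behind all DVH-style metrics. Metrics are computed on the exact voxel
#' multiset (no histogram binning), so the only discretisation is the grid
#' itself.
#'
#' @param grid a [dose_grid()].
#' @param mask a [structure_mask()] sharing the grid's geometry, or `NULL`
#'   for the whole grid.
#' @return Object of class `dose_sample`: doses (Gy, sorted ascending) and
#'   the voxel volume in cc.
#' @export
dose_sample <- function(grid, mask = NULL) {
  stopifnot(inherits(grid, "dose_grid"))
  if (is.null(mask)) {
    doses <- as.numeric(grid$values)
  } else {
    stopifnot(inherits(mask, "structure_mask"))
    if (!same_geometry(grid, mask))
      stop("mask geometry does not match the dose grid", call. = FALSE)
    doses <- grid$values[mask$voxels]
  }
  structure(list(doses = sort(doses), voxel_cc = voxel_volume_cc(grid)),
            class = "dose_sample")
}

stop_if_empty <- function(sample) {
  if (length(sample$doses) == 0L)
    stop("no structure: dose sample is empty", call. = FALSE)
}

#' Dose covering x percent of a structure (Dx%)
#'
#' The largest voxel dose `d` such that at least `x`% of the structure volume
#' receives `>= d`. Interpolation-free: always one of the voxel doses.
#'
#' @param sample a [dose_sample()].
#' @param x percent of structure volume, in (0, 100].
#' @return Dose in Gy.
#' @export
dose_at_volume_pct <- function(sample, x) {
  stop_if_empty(sample)
  stopifnot(x > 0, x <= 100)
  d <- sample$doses  # ascending
  n <- length(d)
  # doses >= d[k] occupy (n - k + 1)/n of the volume; need >= x/100.
  # largest such dose: k = floor(n * (1 - x/100)) + 1
  k <- floor(n * (1 - x / 100) + 1e-9) + 1L
  k <- min(max(k, 1L), n)
  # guard against floating error: ensure the fraction condition holds
  while (k > 1L && (n - k + 1) / n < x / 100 - 1e-12) k <- k - 1L
  d[k]
}

#' Percent of structure volume receiving at least a dose (Vd)
#'
#' Inclusive threshold: voxels with dose `>= d` count.
#'
#' @param sample a [dose_sample()].
#' @param d dose level, Gy (>= 0).
#' @return Percent of structure volume, 0-100.
#' @export
volume_pct_at_dose <- function(sample, d) {
  stop_if_empty(sample)
  stopifnot(d >= 0)
  100 * sum(sample$doses >= d) / length(sample$doses)
}

#' Near-minimum dose to all but a small cold volume
#'
#' The maximum dose `d` such that the volume receiving strictly less than `d`
#' is at most `cold_cc` — i.e. the dose received by all of the structure
#' except its coldest `cold_cc` cubic centimetres. With `cold_cc = 0` this is
#' the plain minimum.
#'
#' @param sample a [dose_sample()].
#' @param cold_cc cold volume to exclude, cc; `0 <= cold_cc <` structure
#'   volume.
#' @return Dose in Gy.
#' @export
near_min_dose <- function(sample, cold_cc = 0.03) {
  stop_if_empty(sample)
  vol <- length(sample$doses) * sample$voxel_cc
  if (cold_cc < 0 || cold_cc >= vol)
    stop("invalid volume: cold_cc must be in [0, structure volume)",
         call. = FALSE)
  # number of coldest voxels we may exclude
  k <- floor(cold_cc / sample$voxel_cc + 1e-9)
  sample$doses[k + 1L]
}

#' Maximum dose over a region
#'
#' @param grid a [dose_grid()].
#' @param region a [structure_mask()], or `NULL` for the whole grid.
#' @return Maximum voxel dose, Gy.
#' @export
max_dose <- function(grid, region = NULL) {
  s <- dose_sample(grid, region)
  stop_if_empty(s)
  s$doses[length(s$doses)]
}

#' Isodose volume at a dose level
#'
#' Volume (cc) of voxels in the region with dose `>= level`; monotone
#' non-increasing in `level`.
#'
#' @param grid a [dose_grid()].
#' @param level dose level, Gy (>= 0).
#' @param region a [structure_mask()], or `NULL` for the whole grid.
#' @return Volume in cc.
#' @export
isodose_volume_cc <- function(grid, level, region = NULL) {
  stopifnot(level >= 0)
  s <- dose_sample(grid, region)
  sum(s$doses >= level) * s$voxel_cc
}

#' Hot volume outside the PTV, as a percentage of PTV volume
#'
#' Volume of voxels outside the PTV with dose strictly greater than `level`,
#' expressed as a percent of the PTV volume (the V105% criterion uses
#' `level = 1.05 * rx_gy`). The strict inequality follows the protocol's
#' ">105%" wording.
#'
#' @param grid a [dose_grid()].
#' @param ptv PTV [structure_mask()].
#' @param level dose level, Gy.
#' @return Percent of PTV volume.
#' @export
hot_volume_outside_pct <- function(grid, ptv, level) {
  stopifnot(inherits(ptv, "structure_mask"))
  if (!same_geometry(grid, ptv))
    stop("mask geometry does not match the dose grid", call. = FALSE)
  n_ptv <- sum(ptv$voxels)
  if (n_ptv == 0L) stop("no structure: PTV mask is empty", call. = FALSE)
  n_hot <- sum(grid$values > level & !ptv$voxels)
  100 * n_hot / n_ptv
}
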