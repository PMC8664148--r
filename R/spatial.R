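#' Conformality index
#'
#' Ratio of the prescription isodose volume (computed over the whole grid, or
#' the body mask when supplied) to the PTV volume.
#'
#' @param grid a [dose_grid()].
#' @param ptv PTV [structure_mask()], nonempty.
#' @param rx_gy prescription dose, Gy (> 0).
#' @param body optional body [structure_mask()] restricting the search.
#' @return Dimensionless index; 1.0 means the Rx isodose volume equals the
#'   PTV volume.
#' @export
conformality_index <- function(grid, ptv, rx_gy, body = NULL) {
  stopifnot(rx_gy > 0)
  ptv_cc <- ptv_volume_checked(ptv)
  isodose_volume_cc(grid, rx_gy, body) / ptv_cc
}

#' R50 dose-falloff index
#'
#' Ratio of the 50%-of-prescription isodose volume to the PTV volume.
#'
#' @inheritParams conformality_index
#' @return Dimensionless index, always `>=` the conformality index.
#' @export
r50 <- function(grid, ptv, rx_gy, body = NULL) {
  stopifnot(rx_gy > 0)
  ptv_cc <- ptv_volume_checked(ptv)
  isodose_volume_cc(grid, 0.5 * rx_gy, body) / ptv_cc
}

ptv_volume_checked <- function(ptv) {
  stopifnot(inherits(ptv, "structure_mask"))
  n <- sum(ptv$voxels)
  if (n == 0L) stop("no structure: PTV mask is empty", call. = FALSE)
  n * voxel_volume_cc(ptv)
}

#' Maximum dose beyond a margin from the PTV (D2cm)
#'
#' Maximum dose over all voxels whose centre lies strictly more than
#' `margin_mm` from the nearest PTV voxel centre, as a percentage of the
#' prescription. With the default 20 mm margin this is the RTOG D2cm metric.
#' When a body mask is supplied the search region is intersected with it
#' ("anywhere in the patient"); otherwise the whole grid is searched.
#'
#' @inheritParams conformality_index
#' @param margin_mm distance margin, mm (default 20).
#' @param dist optional precomputed [distance_from_mask()] field for the PTV
#'   (reused across metrics to avoid recomputation).
#' @return Maximum dose as percent of Rx.
#' @export
d2cm <- function(grid, ptv, rx_gy, margin_mm = 20, body = NULL, dist = NULL) {
  stopifnot(rx_gy > 0)
  if (is.null(dist)) dist <- distance_from_mask(ptv)
  if (!same_geometry(grid, dist))
    stop("distance field geometry does not match the dose grid", call. = FALSE)
  sel <- dist$distances > margin_mm
  if (!is.null(body)) sel <- sel & body$voxels
  if (!any(sel))
    stop("grid too small: no voxel beyond ", margin_mm, " mm from the PTV",
         call. = FALSE)
  100 * max(grid$values[sel]) / rx_gy
}

#' Island-type target classification
#'
#' A target is island-type when its PTV boundary is at least `threshold_mm`
#' (default 10 mm, i.e. 1 cm) from the chest wall at its nearest point. The
#' boundary condition is inclusive: a minimum distance exactly equal to the
#' threshold classifies as island.
#'
#' @param ptv PTV [structure_mask()], nonempty.
#' @param chestwall chest-wall [structure_mask()], or `NULL`.
#' @param threshold_mm distance threshold, mm.
#' @param dist optional precomputed [distance_from_mask()] field for the
#'   chest wall.
#' @return `TRUE`, `FALSE`, or `NA` when no chest-wall mask is available.
#' @export
classify_island <- function(ptv, chestwall, threshold_mm = 10, dist = NULL) {
  stopifnot(inherits(ptv, "structure_mask"))
  if (is.null(chestwall) && is.null(dist)) return(NA)
  if (is.null(dist)) {
    if (sum(chestwall$voxels) == 0L) return(NA)
    dist <- distance_from_mask(chestwall)
  }
  min(dist$distances[ptv$voxels]) >= threshold_mm
}
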