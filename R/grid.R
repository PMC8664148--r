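#' Axis-aligned 3D dose grid
#'
#' Container for a 3D scalar dose field with physical voxel spacing. The
#' physical position of voxel (i, j, k) (1-based R indices) is
#' `origin + (c(i, j, k) - 1) * spacing`, i.e. `origin` is the centre of the
#' first voxel (voxel-centre convention).
#'
#' @param values numeric 3D array of doses in Gy; all finite and >= 0.
#' @param spacing numeric length-3, voxel spacing in mm per axis; all > 0.
#' @param origin numeric length-3, mm coordinates of the centre of voxel
#'   (1,1,1). Defaults to `c(0, 0, 0)`.
#' @return An object of class `dose_grid`.
#' @examples
#' g <- dose_grid(array(60, c(4, 4, 4)), spacing = c(2.5, 2.5, 2.5))
#' voxel_volume_cc(g)
#' @export
dose_grid <- function(values, spacing, origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  if (any(dim(values) < 1L))
    stop("grid needs at least one voxel per axis", call. = FALSE)
  if (!all(is.finite(values)) || any(values < 0))
    stop("dose values must be finite and non-negative", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  check_geometry(spacing, origin)
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "dose_grid")
}

#' Binary structure mask on a dose grid's geometry
#'
#' @param voxels logical (or 0/1 numeric) 3D array marking structure voxels.
#' @param spacing,origin grid geometry, as in [dose_grid()].
#' @param label structure name, e.g. `"PTV"`, `"chestwall"`, `"body"`.
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(voxels, spacing, origin = c(0, 0, 0),
                           label = "structure") {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array", call. = FALSE)
  if (is.numeric(voxels)) {
    if (!all(voxels %in% c(0, 1)))
      stop("mask values must be binary (0/1)", call. = FALSE)
    voxels <- array(voxels == 1, dim(voxels))
  }
  if (!is.logical(voxels))
    stop("mask must be logical or 0/1 numeric", call. = FALSE)
  voxels[is.na(voxels)] <- FALSE
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  check_geometry(spacing, origin)
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 label = as.character(label)[1]),
            class = "structure_mask")
}

check_geometry <- function(spacing, origin) {
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("invalid geometry: spacing must be 3 positive finite values",
         call. = FALSE)
  if (length(origin) != 3L || !all(is.finite(origin)))
    stop("invalid geometry: origin must be 3 finite values", call. = FALSE)
  invisible(TRUE)
}

#' Voxel volume in cubic centimetres
#'
#' @param x a [dose_grid()] or [structure_mask()].
#' @return Scalar volume of one voxel, cc (spacing product in mm^3 / 1000).
#' @export
voxel_volume_cc <- function(x) {
  sp <- x$spacing
  check_geometry(sp, c(0, 0, 0))
  prod(sp) / 1000
}

#' Structure volume in cubic centimetres
#'
#' Voxel-counting volume: number of true voxels times the voxel volume. No
#' partial-volume interpolation is applied.
#'
#' @param mask a [structure_mask()].
#' @return Volume in cc; 0 (with a warning) for an empty mask.
#' @export
structure_volume_cc <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  n <- sum(mask$voxels)
  if (n == 0L)
    warning("mask '", mask$label, "' is empty; volume is 0 cc", call. = FALSE)
  n * voxel_volume_cc(mask)
}

# TRUE iff two of dose_grid / structure_mask / distance_field share
# shape, spacing and origin
same_geometry <- function(a, b, tol = 1e-6) {
  field <- function(x) x$values %||% x$voxels %||% x$distances
  dim_a <- dim(field(a))
  dim_b <- dim(field(b))
  identical(dim_a, dim_b) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<dose_grid> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = " x ")))
  cat(sprintf("  dose range [%.3f, %.3f] Gy, voxel %.6g cc\n",
              min(x$values), max(x$values), voxel_volume_cc(x)))
  invisible(x)
}

#' @export
print.structure_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<structure_mask> '%s' %d x %d x %d, %d voxels (%.3f cc)\n",
              x$label, d[1], d[2], d[3], sum(x$voxels),
              sum(x$voxels) * voxel_volume_cc(x)))
  invisible(x)
}
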