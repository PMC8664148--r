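#' Exact Euclidean distance transform of a structure mask
#'
#' Distance (mm) from every voxel centre to the nearest true voxel centre of
#' the mask, honouring anisotropic spacing. Computed with the separable
#' lower-envelope (parabola) algorithm applied along each axis, which is
#' exact for the squared Euclidean distance.
#'
#' @param mask a nonempty [structure_mask()].
#' @return Object of class `distance_field`: a 3D array of distances (mm)
#'   plus the grid geometry.
#' @export
distance_from_mask <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  if (sum(mask$voxels) == 0L)
    stop("no structure: cannot compute distances from an empty mask",
         call. = FALSE)
  d2 <- array(ifelse(mask$voxels, 0, Inf), dim(mask$voxels))
  for (axis in 1:3) d2 <- edt_pass(d2, axis, mask$spacing[axis])
  structure(list(distances = sqrt(d2), spacing = mask$spacing,
                 origin = mask$origin, label = mask$label),
            class = "distance_field")
}

# One separable pass of the squared EDT along `axis` with spacing w (mm).
edt_pass <- function(d2, axis, w) {
  dm <- dim(d2)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  x <- aperm(d2, perm)
  n <- dim(x)[1]
  m <- prod(dim(x)[2:3])
  dim(x) <- c(n, m)
  for (j in seq_len(m)) {
    col <- x[, j]
    if (any(is.finite(col))) x[, j] <- edt_1d(col, w)
  }
  dim(x) <- dm[perm]
  aperm(x, order(perm))
}

# 1D squared distance transform under squared-Euclidean cost (Felzenszwalb &
# Huttenlocher). f: squared distances (may contain Inf), w: sample spacing.
# Infinite entries carry no parabola; at least one entry must be finite.
edt_1d <- function(f, w) {
  n <- length(f)
  finite <- which(is.finite(f))
  if (length(finite) == 0L) return(f)
  if (n == 1L) return(f)
  w2 <- w * w
  v <- integer(n)      # locations of parabolas in the lower envelope
  z <- numeric(n + 1L) # boundaries between parabolas
  k <- 1L
  v[1L] <- finite[1L]
  z[1L] <- -Inf
  z[2L] <- Inf
  for (q in finite[-1L]) {
    fq <- f[q]
    repeat {
      p <- v[k]
      s <- ((fq + q * q * w2) - (f[p] + p * p * w2)) / (2 * w2 * (q - p))
      if (s <= z[k]) k <- k - 1L else break
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1L] <- Inf
  }
  d <- numeric(n)
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    p <- v[k]
    d[q] <- w2 * (q - p)^2 + f[p]
  }
  d
}

#' @export
print.distance_field <- function(x, ...) {
  cat(sprintf("<distance_field> from '%s', range [%.2f, %.2f] mm\n",
              x$label, min(x$distances), max(x$distances)))
  invisible(x)
}
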