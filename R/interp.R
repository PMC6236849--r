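# Trilinear sampling and separable filtering. All loops are vectorised over
# voxels; these primitives carry every warp, crop and smoothing step in the
# package.

#' Trilinear interpolation of a 3-D array at world points
#'
#' @param arr 3-D numeric array.
#' @param geom geometry the array lives on.
#' @param points N x 3 matrix of world points, mm.
#' @param fill value returned for points outside the grid's voxel-center hull.
#' @return numeric vector of length N.
#' @export
interp_trilinear <- function(arr, geom, points, fill = 0) {
  g <- geometry_of(geom)
  points <- matrix(points, ncol = 3)
  n <- nrow(points)
  # continuous 0-based voxel coordinates
  cx <- (points[, 1] - g$origin[1]) / g$spacing[1]
  cy <- (points[, 2] - g$origin[2]) / g$spacing[2]
  cz <- (points[, 3] - g$origin[3]) / g$spacing[3]
  nx <- g$size[1]; ny <- g$size[2]; nz <- g$size[3]
  inside <- cx >= 0 & cx <= nx - 1 & cy >= 0 & cy <= ny - 1 &
            cz >= 0 & cz <= nz - 1
  out <- rep.int(as.double(fill), n)
  if (!any(inside)) return(out)
  cx <- cx[inside]; cy <- cy[inside]; cz <- cz[inside]
  i0 <- pmin(floor(cx), nx - 2); i0[nx == 1] <- 0
  j0 <- pmin(floor(cy), ny - 2); j0[ny == 1] <- 0
  k0 <- pmin(floor(cz), nz - 2); k0[nz == 1] <- 0
  i0 <- pmax(i0, 0); j0 <- pmax(j0, 0); k0 <- pmax(k0, 0)
  fx <- cx - i0; fy <- cy - j0; fz <- cz - k0
  i1 <- pmin(i0 + 1, nx - 1); j1 <- pmin(j0 + 1, ny - 1); k1 <- pmin(k0 + 1, nz - 1)
  lin <- function(i, j, k) arr[1 + i + nx * (j + ny * k)]
  v <- lin(i0, j0, k0) * (1 - fx) * (1 - fy) * (1 - fz) +
       lin(i1, j0, k0) * fx       * (1 - fy) * (1 - fz) +
       lin(i0, j1, k0) * (1 - fx) * fy       * (1 - fz) +
       lin(i1, j1, k0) * fx       * fy       * (1 - fz) +
       lin(i0, j0, k1) * (1 - fx) * (1 - fy) * fz +
       lin(i1, j0, k1) * fx       * (1 - fy) * fz +
       lin(i0, j1, k1) * (1 - fx) * fy       * fz +
       lin(i1, j1, k1) * fx       * fy       * fz
  out[inside] <- v
  out
}

#' Resample a scalar grid onto a target geometry
#'
#' Trilinear interpolation at the target voxel centers; voxels falling outside
#' the source grid take `fill`. Resampling a grid onto its own geometry is
#' exact (bitwise-equal values).
#'
#' @param grid a [scalar_grid()].
#' @param target_geometry geometry to sample on.
#' @param fill out-of-bounds fill value (finite).
#' @return A `scalar_grid` on `target_geometry` with the source `unit_tag`.
#' @export
resample <- function(grid, target_geometry, fill = 0) {
  if (!is.finite(fill)) stop("fill value must be finite")
  tg <- geometry_of(target_geometry)
  if (same_geometry(grid, tg)) {
    out <- grid
    out$origin <- tg$origin; out$spacing <- tg$spacing
    return(out)
  }
  vals <- interp_trilinear(grid$values, grid, voxel_centers(tg), fill = fill)
  scalar_grid(array(vals, dim = tg$size), tg$origin, tg$spacing,
              unit_tag = grid$unit_tag)
}

#' Sample a displacement field at world points
#'
#' Componentwise trilinear interpolation; points outside the field's grid
#' return zero displacement.
#'
#' @param field a [vector_field()].
#' @param points N x 3 matrix (or length-3 vector) of world points, mm.
#' @return N x 3 matrix of displacements, mm.
#' @export
sample_vector <- function(field, points) {
  points <- matrix(points, ncol = 3)
  if (!all(is.finite(points))) stop("sample points must be finite")
  cbind(interp_trilinear(field$dx, field, points, fill = 0),
        interp_trilinear(field$dy, field, points, fill = 0),
        interp_trilinear(field$dz, field, points, fill = 0))
}

#' Warp an image through a displacement field (pull convention)
#'
#' The field lives on the output geometry; the output at voxel center `x` is
#' the source image sampled at `x + d(x)`.
#'
#' @param image `scalar_grid` to pull values from.
#' @param field `vector_field` on the output geometry.
#' @param fill out-of-bounds fill value.
#' @return `scalar_grid` on the field's geometry.
#' @export
warp_image <- function(image, field, fill = 0) {
  pts <- voxel_centers(field)
  pts <- pts + sample_vector(field, pts)
  vals <- interp_trilinear(image$values, image, pts, fill = fill)
  scalar_grid(array(vals, dim = field$size), field$origin, field$spacing,
              unit_tag = image$unit_tag)
}

# ---- separable filtering -------------------------------------------------

# Apply a symmetric FIR kernel along axis `axis` of a 3-D array with
# zero padding, via one dense matrix product per axis.
filter_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  n <- d[axis]
  r <- (length(kernel) - 1L) / 2L
  # banded n x n convolution matrix, zero-padded boundary
  K <- matrix(0, n, n)
  for (o in -r:r) {
    idx <- seq_len(n)
    src <- idx + o
    ok <- src >= 1 & src <= n
    K[cbind(idx[ok], src[ok])] <- K[cbind(idx[ok], src[ok])] + kernel[o + r + 1]
  }
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = n)
  m <- K %*% m
  a <- array(m, dim = d[perm])
  aperm(a, order(perm))
}

gauss_kernel <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

#' Separable Gaussian smoothing of a 3-D array
#'
#' @param arr 3-D array.
#' @param sigma_mm Gaussian sigma, mm (scalar or per-axis).
#' @param spacing voxel spacing, mm.
#' @param normalize renormalise by the smoothed indicator so values near the
#'   array boundary are not attenuated (`TRUE` for image smoothing); with
#'   `FALSE` the zero-padded convolution is used, so signals decay to zero
#'   outside their support (used for FOV expansion).
#' @return smoothed 3-D array.
#' @export
gauss_smooth <- function(arr, sigma_mm, spacing, normalize = TRUE) {
  sigma_mm <- rep_len(sigma_mm, 3L)
  out <- arr
  for (a in 1:3) {
    s <- sigma_mm[a] / spacing[a]
    if (s > 1e-8) out <- filter_axis(out, gauss_kernel(s), a)
  }
  if (normalize) {
    ones <- array(1, dim = dim(arr))
    for (a in 1:3) {
      s <- sigma_mm[a] / spacing[a]
      if (s > 1e-8) ones <- filter_axis(ones, gauss_kernel(s), a)
    }
    out <- out / pmax(ones, 1e-12)
  }
  out
}

# Local (moving-window) sum over a cubic window of half-width r voxels,
# zero-padded. Used for local means/variances in the LCC machinery.
box_sum <- function(arr, r) {
  k <- rep(1, 2 * r + 1)
  for (a in 1:3) arr <- filter_axis(arr, k, a)
  arr
}
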