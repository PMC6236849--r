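#' Axis-aligned scalar voxel grid
#'
#' The basic image container: a 3-D array of scalar voxel values (HU, Gy,
#' binary or unitless) with world-space geometry. World coordinates are in
#' millimetres; `origin` is the world position of the *center* of voxel
#' `(0,0,0)` (0-based indices) and voxel `(i,j,k)` sits at
#' `origin + c(i,j,k) * spacing`. Axes are axis-aligned (no oblique direction
#' cosines); by convention the third axis is superior--inferior with +z
#' superior.
#'
#' @param values numeric 3-D array, or a vector of length `prod(size)`.
#' @param origin numeric length-3, mm.
#' @param spacing numeric length-3, mm, strictly positive.
#' @param size integer length-3 voxel counts (inferred from `values` when it
#'   is an array).
#' @param unit_tag one of `"HU"`, `"Gy"`, `"binary"`, `"unitless"`.
#' @return A `scalar_grid` object.
#' @export
scalar_grid <- function(values, origin = c(0, 0, 0), spacing = c(1, 1, 1),
                        size = NULL, unit_tag = "unitless") {
  unit_tag <- match.arg(unit_tag, c("HU", "Gy", "binary", "unitless"))
  if (is.null(size)) {
    if (!is.array(values) || length(dim(values)) != 3L)
      stop("`values` must be a 3-D array when `size` is not given")
    size <- dim(values)
  } else {
    size <- as.integer(size)
    if (length(values) != prod(size))
      stop("length(values) [", length(values), "] != prod(size) [", prod(size), "]")
    values <- array(as.double(values), dim = size)
  }
  g <- structure(
    list(values = array(as.double(values), dim = as.integer(size)),
         origin = as.double(origin), spacing = as.double(spacing),
         size = as.integer(size), unit_tag = unit_tag),
    class = "scalar_grid")
  validate_geometry(g)
  if (!all(is.finite(g$values))) stop("grid values must all be finite")
  g
}

validate_geometry <- function(g) {
  if (length(g$origin) != 3L || length(g$spacing) != 3L || length(g$size) != 3L)
    stop("origin, spacing and size must each have length 3")
  if (!all(is.finite(g$origin)) || !all(is.finite(g$spacing)))
    stop("origin and spacing must be finite")
  if (any(g$spacing <= 0)) stop("spacing must be strictly positive")
  if (any(g$size < 1L)) stop("size must be >= 1 on every axis")
  invisible(g)
}

#' Grid geometry descriptor
#'
#' @param origin,spacing,size as in [scalar_grid()].
#' @return A `grid_geometry` list usable as resampling target.
#' @export
grid_geometry <- function(origin, spacing, size) {
  g <- structure(list(origin = as.double(origin), spacing = as.double(spacing),
                      size = as.integer(size)), class = "grid_geometry")
  validate_geometry(g)
  g
}

#' @export
geometry_of <- function(x) UseMethod("geometry_of")
#' @export
geometry_of.scalar_grid <- function(x) grid_geometry(x$origin, x$spacing, x$size)
#' @export
geometry_of.vector_field <- function(x) grid_geometry(x$origin, x$spacing, x$size)
#' @export
geometry_of.grid_geometry <- function(x) x

same_geometry <- function(a, b, tol = 1e-6) {
  a <- geometry_of(a); b <- geometry_of(b)
  all(a$size == b$size) &&
    max(abs(a$origin - b$origin)) <= tol &&
    max(abs(a$spacing - b$spacing)) <= tol
}

#' World coordinates of every voxel center
#'
#' @param geom anything with a geometry (`scalar_grid`, `vector_field`,
#'   `grid_geometry`).
#' @return N x 3 matrix of voxel-center positions (column-major voxel order,
#'   x fastest), mm.
#' @export
voxel_centers <- function(geom) {
  g <- geometry_of(geom)
  idx <- arrayInd(seq_len(prod(g$size)), g$size) - 1L
  sweep(sweep(idx, 2L, g$spacing, `*`), 2L, g$origin, `+`)
}

#' Per-axis world coordinates of voxel centers
#' @noRd
axis_coords <- function(geom) {
  g <- geometry_of(geom)
  lapply(1:3, function(a) g$origin[a] + (seq_len(g$size[a]) - 1) * g$spacing[a])
}

#' Displacement vector field on a voxel grid
#'
#' Stores one 3-vector (mm, world axes) per voxel of the carrier geometry.
#' The convention is *pull*: a field defined on grid A maps a point `x` in A
#' to `x + d(x)` in grid B, so warping an image that lives on B onto A
#' samples the B image at `x + d(x)`. Every field records its `domain`
#' (the grid it lives on) and `codomain` labels to keep directions explicit.
#'
#' @param dx,dy,dz 3-D arrays of per-voxel displacement components, mm.
#' @param origin,spacing as in [scalar_grid()].
#' @param domain,codomain free-text labels (e.g. `"ct"`, `"cbct"`).
#' @return A `vector_field` object.
#' @export
vector_field <- function(dx, dy, dz, origin = c(0, 0, 0), spacing = c(1, 1, 1),
                         domain = "A", codomain = "B") {
  size <- dim(dx)
  if (is.null(size) || length(size) != 3L)
    stop("displacement components must be 3-D arrays")
  if (!identical(dim(dy), size) || !identical(dim(dz), size))
    stop("dx, dy, dz must share dimensions")
  f <- structure(
    list(dx = dx, dy = dy, dz = dz, origin = as.double(origin),
         spacing = as.double(spacing), size = as.integer(size),
         domain = domain, codomain = codomain),
    class = "vector_field")
  validate_geometry(f)
  if (!all(is.finite(dx)) || !all(is.finite(dy)) || !all(is.finite(dz)))
    stop("displacement components must all be finite")
  f
}

#' Zero displacement field on a geometry
#' @param geom target geometry.
#' @inheritParams vector_field
#' @export
zero_field <- function(geom, domain = "A", codomain = "B") {
  g <- geometry_of(geom)
  z <- array(0, dim = g$size)
  vector_field(z, z, z, g$origin, g$spacing, domain, codomain)
}

#' Ordered respiratory-phase image set
#'
#' Ten phase-sorted volumes (0%, 10%, ..., 90%) sharing one geometry, with a
#' designated reference phase (end of inhale, phase 0% by default).
#'
#' @param phases list of `scalar_grid`s with identical geometry.
#' @param reference_index 1-based index of the reference phase.
#' @param n_phases expected number of phases (10 for conventional 4-D sorting).
#' @return A `phase4d_set`.
#' @export
phase4d_set <- function(phases, reference_index = 1L, n_phases = 10L) {
  if (length(phases) != n_phases)
    stop("expected ", n_phases, " phases, got ", length(phases))
  g0 <- geometry_of(phases[[1]])
  for (p in phases) {
    if (!same_geometry(p, g0)) stop("all phases must share identical geometry")
  }
  reference_index <- as.integer(reference_index)
  if (reference_index < 1L || reference_index > length(phases))
    stop("reference_index out of range")
  structure(list(phases = phases, reference_index = reference_index,
                 labels = paste0(seq(0, by = 10, length.out = length(phases)), "%")),
            class = "phase4d_set")
}

#' Binary region-of-interest mask
#'
#' @param grid a binary `scalar_grid` (values in \{0,1\}).
#' @param name structure label, e.g. `"GTV"`, `"cord"`, `"lung"`.
#' @param category `"target"`, `"OAR"` or `"external"`.
#' @param allow_empty permit an all-zero mask.
#' @return An `roi_mask`.
#' @export
roi_mask <- function(grid, name, category = c("target", "OAR", "external"),
                     allow_empty = FALSE) {
  category <- match.arg(category)
  if (!all(grid$values %in% c(0, 1)))
    stop("ROI mask values must be 0/1")
  grid$unit_tag <- "binary"
  if (!allow_empty && sum(grid$values) == 0)
    stop("ROI mask '", name, "' is empty")
  structure(list(grid = grid, name = name, category = category),
            class = "roi_mask")
}

#' Paired registration landmarks
#'
#' @param points_fixed,points_moving N x 3 matrices of world-space points, mm.
#' @param source_convention how the points were read (`"world-mm"` or
#'   `"voxel-index"`).
#' @return A `landmark_set`.
#' @export
landmark_set <- function(points_fixed, points_moving,
                         source_convention = "world-mm") {
  points_fixed <- as.matrix(points_fixed)
  points_moving <- as.matrix(points_moving)
  if (nrow(points_fixed) != nrow(points_moving))
    stop("landmark counts differ: ", nrow(points_fixed), " fixed vs ",
         nrow(points_moving), " moving")
  if (nrow(points_fixed) < 1L) stop("at least one landmark pair required")
  if (ncol(points_fixed) != 3L || ncol(points_moving) != 3L)
    stop("landmark points must have 3 columns")
  if (!all(is.finite(points_fixed)) || !all(is.finite(points_moving)))
    stop("landmark coordinates must be finite")
  structure(list(points_fixed = points_fixed, points_moving = points_moving,
                 source_convention = source_convention, n = nrow(points_fixed)),
            class = "landmark_set")
}

#' Field-of-view region
#'
#' Cylindrical (CBCT-like, axis along z by default) or box-shaped region used
#' for FOV cropping, degradation and pseudo-CT patching.
#'
#' @param shape `"cylinder"` or `"box"`.
#' @param center world center, mm.
#' @param diameter cylinder diameter, mm (cylinder only).
#' @param height cylinder length along its axis, mm (`Inf` = unbounded).
#' @param extents full box edge lengths, mm (box only).
#' @param axis cylinder axis: 1, 2 or 3 (world axis index).
#' @return An `fov_region`.
#' @export
fov_region <- function(shape = c("cylinder", "box"), center = c(0, 0, 0),
                       diameter = NULL, height = Inf, extents = NULL, axis = 3L) {
  shape <- match.arg(shape)
  if (shape == "cylinder") {
    if (is.null(diameter) || diameter <= 0) stop("cylinder needs a positive diameter")
    if (height <= 0) stop("cylinder height must be positive")
  } else {
    if (is.null(extents) || length(extents) != 3L || any(extents <= 0))
      stop("box needs 3 positive extents")
  }
  structure(list(shape = shape, center = as.double(center),
                 diameter = diameter, height = height,
                 extents = if (!is.null(extents)) as.double(extents),
                 axis = as.integer(axis)),
            class = "fov_region")
}

#' Logical inside-FOV test for a set of points
#'
#' @param fov an [fov_region()].
#' @param points N x 3 matrix of world points, mm.
#' @return logical vector of length N.
#' @export
fov_contains <- function(fov, points) {
  points <- matrix(points, ncol = 3)
  if (fov$shape == "cylinder") {
    ax <- fov$axis
    perp <- setdiff(1:3, ax)
    r2 <- (points[, perp[1]] - fov$center[perp[1]])^2 +
          (points[, perp[2]] - fov$center[perp[2]])^2
    ok <- r2 <= (fov$diameter / 2)^2
    if (is.finite(fov$height))
      ok <- ok & abs(points[, ax] - fov$center[ax]) <= fov$height / 2
    ok
  } else {
    abs(points[, 1] - fov$center[1]) <= fov$extents[1] / 2 &
    abs(points[, 2] - fov$center[2]) <= fov$extents[2] / 2 &
    abs(points[, 3] - fov$center[3]) <= fov$extents[3] / 2
  }
}

#' Binary mask of the voxels of a geometry inside an FOV
#' @param fov an [fov_region()].
#' @param geom target geometry.
#' @return 3-D logical array on `geom`.
#' @export
fov_voxel_mask <- function(fov, geom) {
  g <- geometry_of(geom)
  array(fov_contains(fov, voxel_centers(g)), dim = g$size)
}

#' @export
print.scalar_grid <- function(x, ...) {
  cat(sprintf("<scalar_grid [%s]> %d x %d x %d voxels, spacing %s mm\n",
              x$unit_tag, x$size[1], x$size[2], x$size[3],
              paste(signif(x$spacing, 4), collapse = " x ")))
  cat(sprintf("  origin (%s) mm, range [%.4g, %.4g]\n",
              paste(signif(x$origin, 4), collapse = ", "),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.vector_field <- function(x, ...) {
  mag <- sqrt(x$dx^2 + x$dy^2 + x$dz^2)
  cat(sprintf("<vector_field %s -> %s> %d x %d x %d voxels, |d| mean %.3g / max %.3g mm\n",
              x$domain, x$codomain, x$size[1], x$size[2], x$size[3],
              mean(mag), max(mag)))
  invisible(x)
}

#' @export
print.phase4d_set <- function(x, ...) {
  cat(sprintf("<phase4d_set> %d phases (%s), reference %s\n",
              length(x$phases), paste(x$labels, collapse = " "),
              x$labels[x$reference_index]))
  print(x$phases[[1]])
  invisible(x)
}

#' @export
print.landmark_set <- function(x, ...) {
  d <- sqrt(rowSums((x$points_fixed - x$points_moving)^2))
  cat(sprintf("<landmark_set> %d pairs, separation %.2f +/- %.2f mm (read as %s)\n",
              x$n, mean(d), stats::sd(d), x$source_convention))
  invisible(x)
}
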