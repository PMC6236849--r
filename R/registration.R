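# Two-stage deformable registration: exhaustive block matching for a robust
# initial alignment, then dense local-correlation-coefficient (LCC) driven
# demons-style refinement with Gaussian fluid + diffusion regularisation on
# a multiresolution pyramid. The fixed image is the planning CT, the moving
# image the (CB)CT of the day; the output field lives on the fixed geometry
# and maps fixed -> moving (pull convention), so it directly pulls the moving
# image onto the fixed grid.

#' Registration parameters
#'
#' All lengths in mm so settings are geometry-independent.
#'
#' @param block_size_mm stage-1 block edge length.
#' @param search_radius_mm stage-1 exhaustive integer-voxel search radius.
#' @param lcc_radius_vox half-width (voxels) of the local window used for
#'   local normalisation / LCC.
#' @param sigma_fluid_mm Gaussian sigma applied to each demons update.
#' @param sigma_diffusion_mm Gaussian sigma applied to the total field.
#' @param pyramid_levels number of resolution levels (>= 1; finest last).
#' @param max_iter maximum demons iterations per level.
#' @param tol_mm convergence tolerance on the mean update magnitude.
#' @param step update step scale.
#' @param max_step_mm demons force cap per iteration (`NULL` = the pyramid
#'   level's minimum voxel spacing).
#' @param intensity_floor local standard deviation floor (image units) used
#'   in local normalisation, guarding flat (air) regions.
#' @param symmetric drive the update with the mean of the fixed and warped
#'   moving gradients (symmetric forces) rather than the fixed gradient only.
#' @return A `registration_params` list.
#' @export
registration_params <- function(block_size_mm = 20, search_radius_mm = 7.5,
                                lcc_radius_vox = 1L, sigma_fluid_mm = 4,
                                sigma_diffusion_mm = 2, pyramid_levels = 3L,
                                max_iter = 60L, tol_mm = 0.02, step = 0.8,
                                max_step_mm = NULL, intensity_floor = 20,
                                symmetric = TRUE) {
  p <- list(block_size_mm = block_size_mm, search_radius_mm = search_radius_mm,
            lcc_radius_vox = as.integer(lcc_radius_vox),
            sigma_fluid_mm = sigma_fluid_mm,
            sigma_diffusion_mm = sigma_diffusion_mm,
            pyramid_levels = as.integer(pyramid_levels),
            max_iter = as.integer(max_iter), tol_mm = tol_mm, step = step,
            max_step_mm = max_step_mm, intensity_floor = intensity_floor,
            symmetric = isTRUE(symmetric))
  if (any(unlist(p[c(1, 2, 4, 5, 8)]) <= 0) || p$pyramid_levels < 1L)
    stop("registration parameters must be positive; pyramid_levels >= 1")
  class(p) <- "registration_params"
  p
}

#' Crop a CT to the CBCT field of view
#'
#' Voxels outside the FOV are set to the air fill so the registration is not
#' distorted by anatomy the CBCT cannot see. The returned crop record keeps
#' the FOV and the original geometry so the resulting DVF can later be
#' expanded back with [expand_dvf()].
#'
#' @param ct a [scalar_grid()].
#' @param fov an [fov_region()].
#' @param air_fill HU written outside the FOV.
#' @return list with `grid` (masked [scalar_grid()]) and `record`
#'   (`fov`, `full_geometry`, `air_fill`).
#' @export
crop_to_fov <- function(ct, fov, air_fill = -1000) {
  inside <- fov_voxel_mask(fov, ct)
  if (!any(inside)) stop("FOV does not intersect the CT volume")
  v <- ct$values
  v[!inside] <- air_fill
  list(grid = scalar_grid(v, ct$origin, ct$spacing, unit_tag = ct$unit_tag),
       record = structure(list(fov = fov, full_geometry = geometry_of(ct),
                               air_fill = air_fill), class = "crop_record"))
}

#' Local correlation coefficient of two intensity windows
#'
#' Pearson correlation of the voxel intensities in two same-sized windows;
#' defined as 0 when either window has zero variance.
#'
#' @param window_a,window_b numeric arrays/vectors of equal length (>= 2).
#' @return correlation in \[-1, 1\].
#' @export
lcc <- function(window_a, window_b) {
  a <- as.vector(window_a); b <- as.vector(window_b)
  if (length(a) != length(b)) stop("windows must have the same size")
  if (length(a) < 2) stop("windows must contain at least 2 voxels")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 || vb == 0) return(0)
  stats::cov(a, b) / sqrt(va * vb)
}

# ---- internal helpers ----------------------------------------------------

# antialiased resampling of a grid onto a coarser pyramid level
pyramid_level_geometry <- function(geom, factor) {
  g <- geometry_of(geom)
  size <- pmax(ceiling(g$size / factor), 4L)
  grid_geometry(g$origin, g$spacing * factor, size)
}

downsample_image <- function(grid, level_geom) {
  g <- geometry_of(level_geom)
  v <- grid
  if (any(g$spacing > grid$spacing + 1e-9)) {
    sm <- gauss_smooth(grid$values, (g$spacing - grid$spacing) / 2, grid$spacing)
    v <- scalar_grid(sm, grid$origin, grid$spacing, unit_tag = grid$unit_tag)
  }
  resample(v, g, fill = min(grid$values))
}

# per-block sums over non-overlapping b^3 blocks (zero-padded)
block_reduce_sum <- function(arr, b) {
  d <- dim(arr)
  nb <- ceiling(d / b)
  pad <- nb * b
  if (any(pad != d)) {
    tmp <- array(0, pad)
    tmp[1:d[1], 1:d[2], 1:d[3]] <- arr
    arr <- tmp
  }
  a <- array(arr, c(b, nb[1], b, nb[2], b, nb[3]))
  a <- aperm(a, c(1, 3, 5, 2, 4, 6))
  array(colSums(matrix(a, nrow = b^3)), nb)
}

# integer-shift an array, zero-filling exposed voxels
shift_array <- function(arr, s) {
  d <- dim(arr)
  out <- array(0, d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    if (s[a] >= 0) { src[[a]] <- seq_len(d[a] - s[a]) + s[a]; dst[[a]] <- seq_len(d[a] - s[a]) }
    else           { src[[a]] <- seq_len(d[a] + s[a]);        dst[[a]] <- seq_len(d[a] + s[a]) - s[a] }
    if (abs(s[a]) >= d[a]) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

# stage 1: exhaustive integer-voxel block matching; returns a dense field on
# `geom` (one displacement per voxel, mm)
block_match <- function(fixed, moving, geom, params) {
  g <- geometry_of(geom)
  b <- max(2L, round(params$block_size_mm / max(g$spacing)))
  r_vox <- pmax(1L, round(params$search_radius_mm / g$spacing))
  F <- fixed; M <- moving
  n <- b^3
  sF <- block_reduce_sum(F, b); sF2 <- block_reduce_sum(F^2, b)
  varF <- sF2 / n - (sF / n)^2
  nb <- dim(sF)
  best_cc <- array(-Inf, nb)
  best_mag <- array(Inf, nb)
  best <- list(array(0, nb), array(0, nb), array(0, nb))
  shifts <- as.matrix(expand.grid(sx = -r_vox[1]:r_vox[1],
                                  sy = -r_vox[2]:r_vox[2],
                                  sz = -r_vox[3]:r_vox[3]))
  mags <- sqrt((shifts[, 1] * g$spacing[1])^2 + (shifts[, 2] * g$spacing[2])^2 +
               (shifts[, 3] * g$spacing[3])^2)
  keep <- mags <= params$search_radius_mm + 1e-9
  shifts <- shifts[keep, , drop = FALSE]; mags <- mags[keep]
  ord <- order(mags)              # visit small displacements first: ties keep
  for (i in ord) {                # the smaller magnitude (strict improvement)
    s <- shifts[i, ]
    Ms <- shift_array(M, s)
    sM <- block_reduce_sum(Ms, b); sM2 <- block_reduce_sum(Ms^2, b)
    sFM <- block_reduce_sum(F * Ms, b)
    varM <- sM2 / n - (sM / n)^2
    cov <- sFM / n - (sF / n) * (sM / n)
    cc <- cov / sqrt(pmax(varF * varM, 1e-12))
    cc[varF < params$intensity_floor^2 | varM < params$intensity_floor^2] <- 0
    upd <- cc > best_cc + 1e-12
    if (i != ord[1]) upd <- upd & cc > 0.2   # low-confidence blocks stay put
    best_cc[upd] <- cc[upd]
    best_mag[upd] <- mags[i]
    best[[1]][upd] <- s[1] * g$spacing[1]
    best[[2]][upd] <- s[2] * g$spacing[2]
    best[[3]][upd] <- s[3] * g$spacing[3]
  }
  # dense interpolation of the sparse block displacements + smoothing
  block_geom <- grid_geometry(g$origin + (b - 1) / 2 * g$spacing,
                              g$spacing * b, dim(best_cc))
  comp <- lapply(best, function(cmp) {
    cg <- scalar_grid(cmp, block_geom$origin, block_geom$spacing)
    dense <- resample(cg, g, fill = 0)$values
    gauss_smooth(dense, params$block_size_mm / 2, g$spacing)
  })
  comp
}

# local normalisation: (I - local mean) / max(local sd, floor)
local_normalize <- function(arr, r, floor) {
  n <- box_sum(array(1, dim(arr)), r)
  s1 <- box_sum(arr, r)
  s2 <- box_sum(arr^2, r)
  mu <- s1 / n
  sd <- sqrt(pmax(s2 / n - mu^2, 0))
  (arr - mu) / pmax(sd, floor)
}

central_gradient <- function(arr, spacing) {
  gr <- vector("list", 3)
  for (a in 1:3) {
    plus <- shift_array(arr, replace(c(0L, 0L, 0L), a, 1L))
    minus <- shift_array(arr, replace(c(0L, 0L, 0L), a, -1L))
    g <- (plus - minus) / (2 * spacing[a])
    gr[[a]] <- g
  }
  gr
}

#' Deformable registration of a moving image onto a fixed image
#'
#' Stage 1 performs exhaustive integer-voxel block matching at the coarsest
#' pyramid level (ties broken toward the smaller displacement); the sparse
#' block displacements are interpolated to a dense initial field. Stage 2
#' refines it with dense demons-style iterations driven by locally
#' normalised intensities (the local-correlation-coefficient similarity),
#' Gaussian-smoothing each update (fluid) and the total field (diffusion),
#' coarse to fine.
#'
#' @param fixed,moving [scalar_grid()]s with overlapping geometry.
#' @param params a [registration_params()].
#' @param verbose print per-level convergence lines.
#' @return A [vector_field()] on the fixed geometry (fixed -> moving), with
#'   attributes `objective` (tibble: level, iteration, mean LCC, mean update
#'   mm) and `diverged` flag.
#' @export
register <- function(fixed, moving, params = registration_params(),
                     verbose = FALSE) {
  fg <- geometry_of(fixed); mg <- geometry_of(moving)
  lo <- pmax(fg$origin, mg$origin)
  hi <- pmin(fg$origin + (fg$size - 1) * fg$spacing,
             mg$origin + (mg$size - 1) * mg$spacing)
  if (any(lo > hi)) stop("fixed and moving images do not overlap")

  factors <- 2^((params$pyramid_levels - 1):0)
  # a level coarser than ~16 voxels per axis carries no usable structure
  factors <- factors[factors == 1 | apply(outer(factors, fg$size,
    function(f, s) ceiling(s / f)), 1, min) >= 16]
  levels <- length(factors)
  field <- NULL
  objective <- list()
  diverged <- FALSE
  fill_f <- min(fixed$values); fill_m <- min(moving$values)

  for (li in seq_len(levels)) {
    lg <- if (factors[li] > 1) pyramid_level_geometry(fg, factors[li]) else fg
    Fim <- downsample_image(fixed, lg)$values
    Mim <- downsample_image(moving, lg)$values

    if (is.null(field)) {
      init <- block_match(Fim, Mim, lg, params)
      field <- vector_field(init[[1]], init[[2]], init[[3]],
                            lg$origin, lg$spacing, "fixed", "moving")
    } else {
      field <- vector_field(
        resample(scalar_grid(field$dx, field$origin, field$spacing), lg, 0)$values,
        resample(scalar_grid(field$dy, field$origin, field$spacing), lg, 0)$values,
        resample(scalar_grid(field$dz, field$origin, field$spacing), lg, 0)$values,
        lg$origin, lg$spacing, "fixed", "moving")
    }

    r <- params$lcc_radius_vox
    Fn <- local_normalize(Fim, r, params$intensity_floor)
    grad <- central_gradient(Fn, lg$spacing)
    g2 <- grad[[1]]^2 + grad[[2]]^2 + grad[[3]]^2
    max_step <- if (is.null(params$max_step_mm)) min(lg$spacing) else
      params$max_step_mm
    pts <- voxel_centers(lg)
    prev_update <- Inf; grow <- 0L

    for (it in seq_len(params$max_iter)) {
      q <- pts + cbind(as.vector(field$dx), as.vector(field$dy),
                       as.vector(field$dz))
      Mw <- array(interp_trilinear(Mim, lg, q, fill = fill_m), lg$size)
      Mn <- local_normalize(Mw, r, params$intensity_floor)
      diff <- Mn - Fn
      if (params$symmetric) {
        gm <- central_gradient(Mn, lg$spacing)
        hx <- (grad[[1]] + gm[[1]]) / 2
        hy <- (grad[[2]] + gm[[2]]) / 2
        hz <- (grad[[3]] + gm[[3]]) / 2
        h2 <- hx^2 + hy^2 + hz^2
      } else {
        hx <- grad[[1]]; hy <- grad[[2]]; hz <- grad[[3]]; h2 <- g2
      }
      denom <- h2 + diff^2 / max_step^2
      scale <- -diff / pmax(denom, 1e-9)   # descent on local SSD of the
                                           # normalised (LCC) intensities
      ux <- scale * hx; uy <- scale * hy; uz <- scale * hz
      mag <- sqrt(ux^2 + uy^2 + uz^2)
      cap <- pmin(1, max_step / pmax(mag, 1e-9))
      ux <- ux * cap * params$step; uy <- uy * cap * params$step
      uz <- uz * cap * params$step
      sf <- max(params$sigma_fluid_mm, min(lg$spacing))
      sd_ <- max(params$sigma_diffusion_mm, 0.75 * min(lg$spacing))
      ux <- gauss_smooth(ux, sf, lg$spacing)
      uy <- gauss_smooth(uy, sf, lg$spacing)
      uz <- gauss_smooth(uz, sf, lg$spacing)
      dx <- gauss_smooth(field$dx + ux, sd_, lg$spacing)
      dy <- gauss_smooth(field$dy + uy, sd_, lg$spacing)
      dz <- gauss_smooth(field$dz + uz, sd_, lg$spacing)
      field <- vector_field(dx, dy, dz, lg$origin, lg$spacing,
                            "fixed", "moving")
      mean_update <- mean(sqrt(ux^2 + uy^2 + uz^2))
      mean_lcc <- mean(pmin(pmax(Fn * Mn, -1), 1))
      objective[[length(objective) + 1]] <-
        tibble::tibble(level = li, iteration = it,
                       mean_lcc = mean_lcc, mean_update_mm = mean_update)
      if (verbose)
        message(sprintf("level %d iter %2d: mean LCC %.4f, update %.4f mm",
                        li, it, mean_lcc, mean_update))
      if (mean_update < params$tol_mm) break
      if (mean_update > prev_update * 1.05) grow <- grow + 1L else grow <- 0L
      if (grow >= 3L) { diverged <- TRUE; warning("registration diverging; stopped"); break }
      prev_update <- mean_update
    }
  }
  attr(field, "objective") <- dplyr::bind_rows(objective)
  attr(field, "diverged") <- diverged
  field
}

#' Expand a cropped-FOV displacement field to the full CT geometry
#'
#' Embeds the field (zero outside the FOV) in the full geometry and smooths
#' across the FOV boundary with a zero-padded Gaussian so the displacement
#' decays smoothly to zero outside, matching how a registration run on the
#' FOV-cropped CT is extended back to the full field of view.
#'
#' @param dvf a [vector_field()] on the cropped/FOV geometry.
#' @param full_geometry target geometry.
#' @param record crop record from [crop_to_fov()] (supplies the FOV).
#' @param sigma_mm Gaussian boundary-smoothing sigma (0 = hard embed).
#' @return A [vector_field()] on `full_geometry`.
#' @export
expand_dvf <- function(dvf, full_geometry, record, sigma_mm = 5) {
  g <- geometry_of(full_geometry)
  inside <- fov_voxel_mask(record$fov, g)
  embed <- function(cmp) {
    v <- resample(scalar_grid(cmp, dvf$origin, dvf$spacing), g, fill = 0)$values
    v[!inside] <- 0
    if (sigma_mm > 0) v <- gauss_smooth(v, sigma_mm, g$spacing, normalize = FALSE)
    v
  }
  vector_field(embed(dvf$dx), embed(dvf$dy), embed(dvf$dz),
               g$origin, g$spacing, dvf$domain, dvf$codomain)
}

#' Invert a displacement field by fixed-point iteration
#'
#' Solves `b(x) = -f(x + b(x))` from `b = 0` by under-relaxed fixed-point
#' sweeps `b <- b - relax * (f(x + b) + b)` (the plain iteration is the
#' `relax = 1` case; relaxation at 0.5 keeps the sweep contractive wherever
#' the forward Jacobian keeps the map invertible, where the plain iteration
#' can 2-cycle on steep fields). Stops when the mean composition residual
#' `|f(x + b(x)) + b(x)|` drops below `tol_mm` or after `max_iter` sweeps.
#' The residual statistics are attached; failure to reach the tolerance sets
#' a warning flag rather than erroring.
#'
#' @param forward a [vector_field()] (domain A -> codomain B).
#' @param target_geometry geometry of B, where the inverse lives (defaults to
#'   the forward geometry).
#' @param tol_mm convergence tolerance on the mean residual.
#' @param max_iter maximum fixed-point sweeps.
#' @param relax under-relaxation factor in (0, 1].
#' @return A [vector_field()] on `target_geometry` (B -> A) with attributes
#'   `residual` (list: mean, max, n_iter) and `converged`.
#' @export
invert_dvf <- function(forward, target_geometry = NULL, tol_mm = 0.1,
                       max_iter = 100L, relax = 0.5) {
  g <- if (is.null(target_geometry)) geometry_of(forward) else
    geometry_of(target_geometry)
  pts <- voxel_centers(g)
  b <- matrix(0, nrow(pts), 3)
  prev_max <- Inf
  for (it in seq_len(max_iter)) {
    fb <- sample_vector(forward, pts + b)
    res <- sqrt(rowSums((fb + b)^2))
    # once the mean residual is below tolerance, keep sweeping only while
    # the slowest voxels (near steep field gradients) still improve
    if (mean(res) <= tol_mm && prev_max - max(res) < 1e-3) break
    prev_max <- max(res)
    b <- b - relax * (fb + b)
  }
  fb <- sample_vector(forward, pts + b)
  res <- sqrt(rowSums((fb + b)^2))
  out <- vector_field(array(b[, 1], g$size), array(b[, 2], g$size),
                      array(b[, 3], g$size), g$origin, g$spacing,
                      domain = forward$codomain, codomain = forward$domain)
  attr(out, "residual") <- list(mean = mean(res), max = max(res), n_iter = it)
  attr(out, "converged") <- mean(res) <= tol_mm
  out
}

#' Forward/backward field pair
#'
#' Bundles the forward field (on the CT geometry, CT -> CBCT) with its
#' inverse (on the CBCT geometry, CBCT -> CT) and the inversion residual.
#'
#' @param forward a [vector_field()].
#' @param backward_geometry geometry for the inverse (defaults to forward's).
#' @param tol_mm,max_iter passed to [invert_dvf()].
#' @return A `dvf_pair` list: `forward`, `backward`, `residual`, `converged`.
#' @export
dvf_pair <- function(forward, backward_geometry = NULL, tol_mm = 0.1,
                     max_iter = 50L) {
  backward <- invert_dvf(forward, backward_geometry, tol_mm, max_iter)
  structure(list(forward = forward, backward = backward,
                 residual = attr(backward, "residual"),
                 converged = attr(backward, "converged")),
            class = "dvf_pair")
}
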