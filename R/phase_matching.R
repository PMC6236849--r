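# Diaphragm-position extraction and closest-phase pairing between the
# planning 4D-CT and the daily 4D-CBCT. Pairing is driven purely by the
# geometry of the inferior lung boundary, so it is robust to the global
# intensity scaling of CBCT.

#' Diaphragm superior--inferior position of one phase
#'
#' For every axial (x, y) column intersecting the lung mask the most inferior
#' lung voxel is found; the diaphragm position is the mean z coordinate of
#' these column minima over the central 50% of lung columns (columns whose
#' lateral position lies within the per-axis interquartile range of all lung
#' columns), which ignores the curved lateral recesses. Deterministic.
#'
#' @param phase a [scalar_grid()] (only its geometry is used when a mask is
#'   supplied).
#' @param lung_mask an [roi_mask()] on the same geometry, or `NULL` to
#'   threshold the phase image itself at `hu_threshold` inside `fov`.
#' @param hu_threshold HU below which a voxel counts as lung when no mask is
#'   given.
#' @param fov optional [fov_region()] restricting the thresholded search
#'   (used for FOV-truncated CBCT, where outside-FOV air would pollute it).
#' @return SI position, mm (world z of the inferior lung surface).
#' @export
diaphragm_position <- function(phase, lung_mask = NULL, hu_threshold = -400,
                               fov = NULL) {
  g <- geometry_of(phase)
  if (!is.null(lung_mask)) {
    if (!same_geometry(lung_mask$grid, g))
      stop("lung mask geometry does not match the phase image")
    m <- lung_mask$grid$values > 0.5
  } else {
    m <- phase$values < hu_threshold
    if (!is.null(fov)) m <- m & fov_voxel_mask(fov, g)
    # drop voxels on the lateral image boundary (outside-body air)
    m[c(1, g$size[1]), , ] <- FALSE
    m[, c(1, g$size[2]), ] <- FALSE
  }
  if (!any(m)) stop("lung mask is empty")
  # most inferior lung voxel per (x, y) column; a valid lung voxel must have
  # non-lung tissue below it, which rejects columns of outside-body air in
  # the thresholded (mask-free) path
  zmin_idx <- apply(m, c(1, 2), function(col) {
    f <- which(!col)
    if (length(f) == 0L) return(NA_integer_)
    t <- which(col)
    t <- t[t > f[1]]
    if (length(t)) t[1] else NA_integer_
  })
  cols <- which(!is.na(zmin_idx), arr.ind = TRUE)
  qx <- stats::quantile(cols[, 1], c(0.25, 0.75), type = 1)
  qy <- stats::quantile(cols[, 2], c(0.25, 0.75), type = 1)
  central <- cols[, 1] >= qx[1] & cols[, 1] <= qx[2] &
             cols[, 2] >= qy[1] & cols[, 2] <= qy[2]
  if (!any(central)) central <- rep(TRUE, nrow(cols))
  kz <- zmin_idx[cols[central, , drop = FALSE]]
  mean(g$origin[3] + (kz - 1) * g$spacing[3])
}

#' Match daily CBCT phases to the closest planning CT phases
#'
#' Each CBCT phase is paired with the CT phase whose diaphragm position is
#' nearest (many-to-one mappings allowed; ties go to the smaller CT phase
#' index). Equivalent to brute-force minimisation over all CT phases.
#'
#' @param ct4d,cbct4d [phase4d_set()]s.
#' @param lung_mask_ct optional [roi_mask()] for the CT phases.
#' @param lung_mask_cbct optional [roi_mask()] for the CBCT phases; when
#'   `NULL` the CBCT lung is found by HU thresholding inside `fov`.
#' @param hu_threshold,fov passed to [diaphragm_position()] for thresholded
#'   extraction.
#' @return A tibble (class `phase_pairing`) with one row per CBCT phase:
#'   `cbct_phase`, `ct_phase` (1-based indices), `d_cbct_mm`, `d_ct_mm`,
#'   `delta_mm`.
#' @export
match_phases <- function(ct4d, cbct4d, lung_mask_ct = NULL,
                         lung_mask_cbct = NULL, hu_threshold = -400,
                         fov = NULL) {
  d_ct <- vapply(ct4d$phases, diaphragm_position, 0,
                 lung_mask = lung_mask_ct, hu_threshold = hu_threshold)
  d_cbct <- vapply(cbct4d$phases, diaphragm_position, 0,
                   lung_mask = lung_mask_cbct, hu_threshold = hu_threshold,
                   fov = fov)
  pairs <- vapply(d_cbct, function(d) which.min(abs(d_ct - d)), 0L)
  out <- tibble::tibble(
    cbct_phase = seq_along(d_cbct),
    ct_phase = pairs,
    d_cbct_mm = d_cbct,
    d_ct_mm = d_ct[pairs],
    delta_mm = abs(d_cbct - d_ct[pairs]))
  class(out) <- c("phase_pairing", class(out))
  out
}
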