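# Pseudo-CT synthesis: plan-CT HU values (after intensity overrides) are
# pulled onto the treatment-day geometry through the backward DVF; voxels
# outside the CBCT field of view are patched with the matching-phase plan CT
# shifted by the recorded couch correction.

#' Intensity override specification
#'
#' @param roi an [roi_mask()] on the plan-CT geometry.
#' @param value HU to assign inside the ROI (finite).
#' @return An `override_spec`.
#' @export
override_spec <- function(roi, value) {
  if (!is.finite(value)) stop("override HU value must be finite")
  structure(list(roi = roi, value = as.double(value)), class = "override_spec")
}

#' Apply HU intensity overrides to a CT
#'
#' Overrides are applied in list order, so a later override wins on any
#' voxel covered by several ROIs (e.g. dental fill inside an artifact
#' region).
#'
#' @param ct a [scalar_grid()].
#' @param overrides list of [override_spec()]s on the CT geometry.
#' @return The overridden [scalar_grid()].
#' @export
apply_overrides <- function(ct, overrides = list()) {
  if (inherits(overrides, "override_spec")) overrides <- list(overrides)
  v <- ct$values
  for (ov in overrides) {
    if (!same_geometry(ov$roi$grid, ct))
      stop("override ROI '", ov$roi$name, "' is not on the CT geometry")
    v[ov$roi$grid$values > 0.5] <- ov$value
  }
  scalar_grid(v, ct$origin, ct$spacing, unit_tag = ct$unit_tag)
}

#' Generate a pseudo-CT on the treatment-day geometry
#'
#' Inside the CBCT field of view, each day voxel `x` takes the plan-CT value
#' sampled at `x + b(x)` through the backward DVF (CBCT -> CT). Outside the
#' FOV, where the CBCT carries no anatomy, the value is patched from the
#' matching-phase plan CT resampled rigidly with the recorded couch shift
#' applied, assuming that region did not deform.
#'
#' @param ct_plan plan CT [scalar_grid()] (already overridden if needed).
#' @param backward_dvf [vector_field()] on the day geometry (day -> plan CT).
#' @param day_geometry output geometry (defaults to the DVF geometry).
#' @param fov [fov_region()] of the CBCT, or `NULL` for full coverage.
#' @param patch_phase_ct plan-CT phase used to patch outside the FOV
#'   (required whenever the FOV does not cover the full day grid).
#' @param couch_shift_mm recorded couch correction applied to the patch
#'   image, mm (patient content appears shifted by `+couch_shift_mm`).
#' @param air_fill HU for day voxels mapping outside the plan CT.
#' @return A [scalar_grid()] with `unit_tag = "HU"` on the day geometry.
#' @export
generate_pseudo_ct <- function(ct_plan, backward_dvf, day_geometry = NULL,
                               fov = NULL, patch_phase_ct = NULL,
                               couch_shift_mm = c(0, 0, 0),
                               air_fill = -1000) {
  g <- if (is.null(day_geometry)) geometry_of(backward_dvf) else
    geometry_of(day_geometry)
  if (!same_geometry(backward_dvf, g))
    stop("backward DVF must live on the day geometry")
  pts <- voxel_centers(g)
  vals <- interp_trilinear(ct_plan$values, ct_plan,
                           pts + sample_vector(backward_dvf, pts),
                           fill = air_fill)
  if (!is.null(fov)) {
    inside <- fov_contains(fov, pts)
    if (!all(inside)) {
      if (is.null(patch_phase_ct))
        stop("FOV does not cover the day grid: a patch_phase_ct is required")
      patch_pts <- sweep(pts[!inside, , drop = FALSE], 2L, couch_shift_mm, `-`)
      vals[!inside] <- interp_trilinear(patch_phase_ct$values, patch_phase_ct,
                                        patch_pts, fill = air_fill)
    }
  }
  scalar_grid(array(vals, g$size), g$origin, g$spacing, unit_tag = "HU")
}
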