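# Synthetic breathing-thorax phantom.
#
# The reference anatomy (end of inhale) is an analytic HU function: elliptic
# body cylinder, two lung ellipsoids cut flat at the diaphragm, a spinal-cord
# cylinder, a spherical tumor and vessel-like bright spheroids inside the
# lung that carry the landmarks. Tissue boundaries are blended over a small
# edge width so images are smooth enough for gradient-based registration and
# for consistent trilinear warping.
#
# Breathing is a 1-D superior--inferior motion: phase p in 0..9 has scale
# s(p) = (1 - cos(2*pi*p/10)) / 2, zero at the reference (end of inhale) and
# one at end of exhale. The *pull* field from phase to reference is defined
# analytically in Eulerian form; its exact inverse (the reference-to-phase
# field) is obtained by per-point fixed-point solution of the same analytic
# law, not by registration.

phase_scale <- function(phase_index, n_phases = 10L)
  (1 - cos(2 * pi * (phase_index - 1) / n_phases)) / 2

smoothstep01 <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t * t * (3 - 2 * t)
}

#' Phantom specification
#'
#' Defaults give a 64^3 grid at 2.5 mm isotropic spacing centered on the
#' origin, thorax-like HU constants, a 10 mm diaphragm excursion and an
#' 8 mm tumor excursion.
#'
#' @param size,spacing,origin grid geometry (origin defaults to centering the
#'   grid on (0,0,0)).
#' @param body_halfaxes elliptic body-cylinder half-axes (x, y), mm.
#' @param lung_center_right,lung_halfaxes right-lung ellipsoid center and
#'   half-axes, mm (the left lung is mirrored in x).
#' @param hu named HU constants per tissue.
#' @param cord_center,cord_radius spinal-cord cylinder (x,y) center and
#'   radius, mm.
#' @param tumor_center,tumor_radius tumor sphere at reference phase, mm.
#' @param diaphragm_z diaphragm rest (end-of-inhale) superior--inferior
#'   position, mm; the lungs are cut flat here.
#' @param sub_diaphragm_plateau,sub_diaphragm_decay extent of full-amplitude
#'   motion below the diaphragm and of its decay to rest in the abdomen, mm
#'   (their sum must leave the inferior image boundary static).
#' @param amp_diaphragm diaphragm excursion amplitude A_d, mm.
#' @param amp_tumor tumor excursion amplitude A_t, mm (`NULL` = follow the
#'   diaphragm taper at the tumor position).
#' @param n_phases number of respiratory phases (10).
#' @param n_vessels number of vessel-like landmark spheroids per lung.
#' @param vessel_radius spheroid radius, mm.
#' @param edge_mm tissue-boundary blend width, mm.
#' @param seed integer seed for vessel placement.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(size = c(64, 64, 64), spacing = c(2.5, 2.5, 2.5),
                         origin = NULL,
                         body_halfaxes = c(70, 55),
                         lung_center_right = c(32, 0, 10),
                         lung_halfaxes = c(24, 36, 60),
                         hu = c(air = -1000, lung = -750, soft = 40,
                                cord = 100, tumor = 60, vessel = 0),
                         cord_center = c(0, 38), cord_radius = 6,
                         tumor_center = c(32, 0, -10), tumor_radius = 10,
                         diaphragm_z = -40,
                         sub_diaphragm_plateau = 8, sub_diaphragm_decay = 18,
                         amp_diaphragm = 10, amp_tumor = 8,
                         n_phases = 10L, n_vessels = 6L, vessel_radius = 4,
                         edge_mm = 3, seed = 20181010L) {
  if (is.null(origin)) origin <- -(size - 1) * spacing / 2
  if (amp_diaphragm < 0 || (!is.null(amp_tumor) && amp_tumor < 0))
    stop("excursion amplitudes must be >= 0")
  if (n_phases != 10L) stop("n_phases must be 10 (conventional 4-D phase sorting)")
  spec <- list(size = as.integer(size), spacing = as.double(spacing),
               origin = as.double(origin),
               body_halfaxes = body_halfaxes,
               lung_center_right = lung_center_right,
               lung_halfaxes = lung_halfaxes, hu = hu,
               cord_center = cord_center, cord_radius = cord_radius,
               tumor_center = tumor_center, tumor_radius = tumor_radius,
               diaphragm_z = diaphragm_z,
               sub_diaphragm_plateau = sub_diaphragm_plateau,
               sub_diaphragm_decay = sub_diaphragm_decay,
               amp_diaphragm = amp_diaphragm, amp_tumor = amp_tumor,
               n_phases = as.integer(n_phases), n_vessels = as.integer(n_vessels),
               vessel_radius = vessel_radius, edge_mm = edge_mm,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  spec
}

# lung apex (superior extent), mm
lung_apex_z <- function(spec) spec$lung_center_right[3] + spec$lung_halfaxes[3]

# blended membership in [0,1] from an approximate signed distance (mm,
# positive inside)
edge_blend <- function(sdist, edge_mm) smoothstep01(sdist / edge_mm + 0.5)

# approximate signed distance to an ellipsoid (positive inside)
ellipsoid_sdist <- function(p, center, halfaxes) {
  rho <- sqrt(((p[, 1] - center[1]) / halfaxes[1])^2 +
              ((p[, 2] - center[2]) / halfaxes[2])^2 +
              ((p[, 3] - center[3]) / halfaxes[3])^2)
  (1 - rho) * min(halfaxes)
}

# approximate signed distance to one lung (positive inside): elliptic
# cross-section, flat base at the diaphragm, ellipsoidal dome above the
# center so every lung-containing column reaches the diaphragm plane
lung_sdist <- function(p, center, halfaxes, diaphragm_z) {
  dz <- p[, 3] - center[3]
  shrink <- sqrt(pmax(1 - (pmax(dz, 0) / halfaxes[3])^2, 0))
  rho <- sqrt(((p[, 1] - center[1]) / halfaxes[1])^2 +
              ((p[, 2] - center[2]) / halfaxes[2])^2)
  sd_xy <- (shrink - rho) * min(halfaxes[1:2])
  pmin(sd_xy, p[, 3] - diaphragm_z)
}

# deterministic vessel placement inside the right lung (reference frame)
vessel_centers <- function(spec) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  ctr <- spec$lung_center_right
  ha <- spec$lung_halfaxes * 0.6        # keep well inside the lung
  pts <- matrix(NA_real_, 0, 3)
  guard <- 0L
  while (nrow(pts) < spec$n_vessels && guard < 1000L) {
    guard <- guard + 1L
    cand <- ctr + stats::runif(3, -1, 1) * ha
    sd <- lung_sdist(matrix(cand, 1, 3), ctr, spec$lung_halfaxes,
                     spec$diaphragm_z)
    if (sd < spec$vessel_radius + 2 * spec$edge_mm) next
    # stay clear of the tumor motion capsule
    seg <- pmin(pmax(cand[3] - spec$tumor_center[3], 0), tumor_amp(spec))
    dt <- sqrt(sum((cand - (spec$tumor_center + c(0, 0, seg)))^2))
    if (dt < spec$tumor_radius + tumor_blend_margin(spec) + spec$vessel_radius) next
    pts <- rbind(pts, cand)
  }
  if (nrow(pts) < spec$n_vessels)
    stop("could not place ", spec$n_vessels, " vessels inside the lung")
  pts
}

tumor_amp <- function(spec) {
  if (!is.null(spec$amp_tumor)) return(spec$amp_tumor)
  spec$amp_diaphragm * diaphragm_taper(spec$tumor_center[3], spec)
}

tumor_blend_margin <- function(spec) max(2 * spec$edge_mm, 6)

# taper of the diaphragm-driven displacement: 0 at the lung apex, rising
# linearly to 1 at the diaphragm, full over a short sub-diaphragmatic
# plateau, then decaying to 0 in the abdomen so the field vanishes before
# the inferior image boundary
diaphragm_taper <- function(z, spec) {
  plateau <- spec$sub_diaphragm_plateau %||% 8
  decay <- spec$sub_diaphragm_decay %||% 18
  apex <- lung_apex_z(spec)
  up <- pmin(pmax((apex - z) / (apex - spec$diaphragm_z), 0), 1)
  dn <- pmin(pmax((z - (spec$diaphragm_z - plateau - decay)) / decay, 0), 1)
  pmin(up, dn)
}

# capsule blend weight around the tumor motion path (1 on the plateau)
tumor_capsule_weight <- function(p, spec) {
  a_t <- tumor_amp(spec)
  seg <- pmin(pmax(p[, 3] - spec$tumor_center[3], 0), a_t)
  ax <- spec$tumor_center[1]; ay <- spec$tumor_center[2]
  d <- sqrt((p[, 1] - ax)^2 + (p[, 2] - ay)^2 +
            (p[, 3] - (spec$tumor_center[3] + seg))^2)
  w <- tumor_blend_margin(spec)
  plateau <- spec$tumor_radius + spec$edge_mm
  smoothstep01(1 - (d - plateau) / w)
}

# superior displacement magnitude field D(y), mm, at unit phase scale
motion_magnitude <- function(p, spec) {
  b <- tumor_capsule_weight(p, spec)
  (1 - b) * spec$amp_diaphragm * diaphragm_taper(p[, 3], spec) +
    b * tumor_amp(spec)
}

# analytic pull field phase -> reference, evaluated at points (Eulerian):
# v(y) = -s * D(y) * e_z
pull_to_ref_at <- function(p, s, spec) -s * motion_magnitude(p, spec)

# exact inverse displacement r(x) with r = -v(x + r), solved by fixed point
ref_to_phase_at <- function(p, s, spec, tol = 1e-10, max_iter = 200L) {
  r <- numeric(nrow(p))
  q <- p
  for (i in seq_len(max_iter)) {
    q[, 3] <- p[, 3] + r
    r_new <- s * motion_magnitude(q, spec)
    if (max(abs(r_new - r)) < tol) { r <- r_new; break }
    r <- r_new
  }
  r
}

# analytic reference-frame HU at world points (vectorised)
reference_hu_at <- function(p, spec, vessels = NULL, tumor_radius = NULL) {
  hu <- spec$hu
  e <- spec$edge_mm
  if (is.null(tumor_radius)) tumor_radius <- spec$tumor_radius
  val <- rep.int(hu[["air"]], nrow(p))
  # body: elliptic cylinder along z
  rho_b <- sqrt((p[, 1] / spec$body_halfaxes[1])^2 +
                (p[, 2] / spec$body_halfaxes[2])^2)
  w_body <- edge_blend((1 - rho_b) * min(spec$body_halfaxes), e)
  val <- val + w_body * (hu[["soft"]] - hu[["air"]])
  # lungs: mirrored, flat base at the diaphragm, domed apex
  ctr <- spec$lung_center_right
  sd_lung <- pmax(lung_sdist(p, ctr, spec$lung_halfaxes, spec$diaphragm_z),
                  lung_sdist(p, c(-ctr[1], ctr[2:3]), spec$lung_halfaxes,
                             spec$diaphragm_z))
  w_lung <- edge_blend(sd_lung, e)
  val <- val + w_body * w_lung * (hu[["lung"]] - hu[["soft"]])
  # vessels (bright spheroids inside the lung)
  if (!is.null(vessels) && nrow(vessels) > 0) {
    for (i in seq_len(nrow(vessels))) {
      dv <- spec$vessel_radius -
        sqrt((p[, 1] - vessels[i, 1])^2 + (p[, 2] - vessels[i, 2])^2 +
             (p[, 3] - vessels[i, 3])^2)
      val <- val + w_lung * edge_blend(dv, e) * (hu[["vessel"]] - hu[["lung"]])
    }
  }
  # spinal cord: cylinder along z, posterior midline (outside the lungs)
  dc <- spec$cord_radius - sqrt((p[, 1] - spec$cord_center[1])^2 +
                                (p[, 2] - spec$cord_center[2])^2)
  val <- val + w_body * edge_blend(dc, e) * (hu[["cord"]] - hu[["soft"]])
  # tumor: sphere inside the lung
  dt <- tumor_radius - sqrt((p[, 1] - spec$tumor_center[1])^2 +
                            (p[, 2] - spec$tumor_center[2])^2 +
                            (p[, 3] - spec$tumor_center[3])^2)
  val <- val + edge_blend(dt, e) * (hu[["tumor"]] - val)
  val
}

check_tumor_in_lung <- function(spec) {
  a_t <- tumor_amp(spec)
  ctr <- spec$lung_center_right
  for (s in c(0, 0.5, 1)) {
    c_p <- spec$tumor_center + c(0, 0, s * a_t)
    sd <- lung_sdist(matrix(c_p, 1, 3), ctr, spec$lung_halfaxes,
                     spec$diaphragm_z + s * spec$amp_diaphragm)
    if (sd < spec$tumor_radius)
      stop("tumor exits the lung under motion (phase scale ", s, ")")
  }
  invisible(TRUE)
}

#' Generate a 4-D CT phantom with exact ground-truth deformations
#'
#' Builds the 10-phase breathing thorax: per-phase HU volumes evaluated
#' analytically (no resampling error), exact pull fields in both directions,
#' ROI masks on the reference phase, and vessel-center landmark pairs per
#' phase.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `ct4d` ([phase4d_set()]), `dvf_to_ref`
#'   (list of [vector_field()] on the reference grid; warping phase p with
#'   `dvf_to_ref[[p]]` reproduces the reference image), `dvf_to_phase`
#'   (fields on the phase grids pulling the reference image forward), `rois`
#'   (named list of [roi_mask()] on the reference grid), `landmarks` (list of
#'   [landmark_set()], fixed = reference positions, moving = phase-p
#'   positions), `vessels` (reference vessel centers) and `spec`.
#' @export
make_4dct <- function(spec = phantom_spec()) {
  check_tumor_in_lung(spec)
  geom <- grid_geometry(spec$origin, spec$spacing, spec$size)
  pts <- voxel_centers(geom)
  vessels <- if (spec$n_vessels > 0) vessel_centers(spec) else NULL

  phases <- vector("list", spec$n_phases)
  dvf_to_ref <- vector("list", spec$n_phases)
  dvf_to_phase <- vector("list", spec$n_phases)
  landmarks <- vector("list", spec$n_phases)
  zero <- array(0, dim = geom$size)

  for (p in seq_len(spec$n_phases)) {
    s <- phase_scale(p, spec$n_phases)
    lab <- paste0("phase", (p - 1) * 10)
    vz <- pull_to_ref_at(pts, s, spec)
    q <- pts; q[, 3] <- pts[, 3] + vz
    phases[[p]] <- scalar_grid(array(reference_hu_at(q, spec, vessels), geom$size),
                               geom$origin, geom$spacing, unit_tag = "HU")
    dvf_to_phase[[p]] <- vector_field(zero, zero, array(vz, geom$size),
                                      geom$origin, geom$spacing,
                                      domain = lab, codomain = "reference")
    rz <- ref_to_phase_at(pts, s, spec)
    dvf_to_ref[[p]] <- vector_field(zero, zero, array(rz, geom$size),
                                    geom$origin, geom$spacing,
                                    domain = "reference", codomain = lab)
    if (!is.null(vessels)) {
      mv <- vessels
      mv[, 3] <- vessels[, 3] + ref_to_phase_at(vessels, s, spec)
      landmarks[[p]] <- landmark_set(vessels, mv)
    }
  }

  ct4d <- phase4d_set(phases, reference_index = 1L, n_phases = spec$n_phases)

  mask_from <- function(inside, name, category)
    roi_mask(scalar_grid(array(as.double(inside), geom$size), geom$origin,
                         geom$spacing, unit_tag = "binary"),
             name, category)
  rho_b <- sqrt((pts[, 1] / spec$body_halfaxes[1])^2 +
                (pts[, 2] / spec$body_halfaxes[2])^2)
  ctr <- spec$lung_center_right
  sd_lung <- pmax(lung_sdist(pts, ctr, spec$lung_halfaxes, spec$diaphragm_z),
                  lung_sdist(pts, c(-ctr[1], ctr[2:3]), spec$lung_halfaxes,
                             spec$diaphragm_z))
  d_t <- sqrt((pts[, 1] - spec$tumor_center[1])^2 +
              (pts[, 2] - spec$tumor_center[2])^2 +
              (pts[, 3] - spec$tumor_center[3])^2)
  d_c <- sqrt((pts[, 1] - spec$cord_center[1])^2 +
              (pts[, 2] - spec$cord_center[2])^2)
  rois <- list(
    body = mask_from(rho_b <= 1, "body", "external"),
    lung = mask_from(sd_lung >= 0, "lung", "OAR"),
    cord = mask_from(d_c <= spec$cord_radius & rho_b <= 1, "cord", "OAR"),
    gtv  = mask_from(d_t <= spec$tumor_radius, "GTV", "target"))

  list(ct4d = ct4d, dvf_to_ref = dvf_to_ref, dvf_to_phase = dvf_to_phase,
       rois = rois, landmarks = landmarks, vessels = vessels, spec = spec)
}

#' CBCT degradation specification
#'
#' @param noise_sd additive Gaussian noise standard deviation, HU.
#' @param scale,offset global intensity transform `HU * scale + offset`.
#' @param fov an [fov_region()] or `NULL` (full coverage).
#' @param shift_mm per-fraction rigid setup offset, mm (applied to the image
#'   content, i.e. the patient appears shifted by `+shift_mm`).
#' @param air_fill HU written outside the FOV.
#' @param seed integer noise seed.
#' @return A `cbct_degrade_spec`.
#' @export
cbct_degrade_spec <- function(noise_sd = 20, scale = 0.95, offset = -10,
                              fov = fov_region("cylinder", diameter = 120),
                              shift_mm = c(0, 0, 0), air_fill = -1000,
                              seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(noise_sd = noise_sd, scale = scale, offset = offset,
                 fov = fov, shift_mm = as.double(shift_mm),
                 air_fill = air_fill, seed = as.integer(seed)),
            class = "cbct_degrade_spec")
}

#' Degrade a 4-D CT into a CBCT-like set
#'
#' Applies, in order: rigid setup shift of the image content, global intensity
#' scale/offset, additive Gaussian noise, and cylindrical/box FOV truncation
#' (outside voxels set to the air fill). Fully reproducible given the seed.
#'
#' @param ct4d a [phase4d_set()].
#' @param spec a [cbct_degrade_spec()].
#' @return A degraded [phase4d_set()] on the same geometry.
#' @export
degrade_to_cbct <- function(ct4d, spec = cbct_degrade_spec()) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  geom <- geometry_of(ct4d$phases[[1]])
  outside <- if (!is.null(spec$fov)) !fov_voxel_mask(spec$fov, geom) else
    array(FALSE, geom$size)
  shift <- any(spec$shift_mm != 0)
  pts <- if (shift) sweep(voxel_centers(geom), 2L, spec$shift_mm, `-`) else NULL
  out <- lapply(ct4d$phases, function(ph) {
    v <- ph$values
    if (shift)
      v <- array(interp_trilinear(v, geom, pts, fill = spec$air_fill), geom$size)
    v <- v * spec$scale + spec$offset
    if (spec$noise_sd > 0)
      v <- v + array(stats::rnorm(prod(geom$size), 0, spec$noise_sd), geom$size)
    v[outside] <- spec$air_fill
    scalar_grid(v, geom$origin, geom$spacing, unit_tag = "HU")
  })
  phase4d_set(out, ct4d$reference_index, length(out))
}

#' Simulate a treatment course with daily 4-D CBCTs
#'
#' Generates the planning 4-D CT once, then for each fraction regenerates the
#' day's anatomy with optional tumor shrinkage and setup drift, and degrades
#' it to a 4-D CBCT. Tumor shrinkage is applied to the radius so that each
#' fraction's tumor volume is `(1 - shrink_per_fraction)` times the
#' previous fraction's. Schedule dates advance one weekday-agnostic day per
#' fraction.
#'
#' @param plan_spec [phantom_spec()] for the planning CT.
#' @param n_fractions number of fractions (>= 1).
#' @param drift_per_fraction rigid setup drift added per fraction, mm
#'   (length 3; fraction f is shifted by `(f-1) * drift_per_fraction`).
#' @param shrink_per_fraction fractional tumor *volume* loss per fraction.
#' @param degrade a [cbct_degrade_spec()] template (per-fraction seed and
#'   shift are derived from it).
#' @param patient_id identifier written into the treatment record.
#' @param start_date first fraction date.
#' @return list with `record` (a [treatment_record()]), `plan` (the
#'   [make_4dct()] output for the planning CT) and `fractions` (per fraction:
#'   `cbct4d`, noiseless `truth4d`, ground-truth fields, day ROIs and the
#'   applied shift).
#' @export
make_course <- function(plan_spec = phantom_spec(), n_fractions = 5L,
                        drift_per_fraction = c(0, 0, 0),
                        shrink_per_fraction = 0,
                        degrade = cbct_degrade_spec(),
                        patient_id = "phantom-001",
                        start_date = as.Date("2018-10-01")) {
  if (n_fractions < 1L) stop("n_fractions must be >= 1")
  plan <- make_4dct(plan_spec)
  fractions <- vector("list", n_fractions)
  for (f in seq_len(n_fractions)) {
    fspec <- plan_spec
    fspec$tumor_radius <- plan_spec$tumor_radius *
      (1 - shrink_per_fraction)^((f - 1) / 3)
    day <- make_4dct(fspec)
    shift <- (f - 1) * drift_per_fraction
    dspec <- degrade
    dspec$shift_mm <- degrade$shift_mm + shift
    dspec$seed <- degrade$seed + 1000L * f
    fractions[[f]] <- list(
      cbct4d = degrade_to_cbct(day$ct4d, dspec),
      truth4d = day$ct4d,
      dvf_to_ref = day$dvf_to_ref,
      rois = day$rois,
      landmarks = day$landmarks,
      shift_mm = shift,
      degrade = dspec)
  }
  record <- treatment_record(
    patient_id = patient_id,
    fractions = tibble::tibble(
      index = seq_len(n_fractions),
      date = start_date + seq_len(n_fractions) - 1L,
      couch_dx = vapply(fractions, function(x) -x$shift_mm[1], 0),
      couch_dy = vapply(fractions, function(x) -x$shift_mm[2], 0),
      couch_dz = vapply(fractions, function(x) -x$shift_mm[3], 0),
      status = "PENDING"))
  list(record = record, plan = plan, fractions = fractions)
}
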