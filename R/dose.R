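# Simplified dose engine and the warping/accumulation chain. The engine is a
# non-clinical stand-in for a treatment planning system: divergent
# rectangular beams with exponential attenuation along the radiological path
# (ray marching through HU-derived density) and inverse-square falloff. It
# produces smooth, anatomy-dependent dose distributions with the right
# qualitative behaviour (build-free exponential depth dose, density
# sensitivity) for exercising warping, accumulation and DVH analysis.

#' Rectangular divergent beam
#'
#' @param isocenter beam isocenter, mm.
#' @param direction central-axis direction (need not be normalised).
#' @param field_size field edge lengths at the isocenter plane, mm (length 2).
#' @param sad source--axis distance, mm (source sits at
#'   `isocenter - sad * direction`).
#' @param weight relative beam weight (>= 0).
#' @param mu linear attenuation coefficient per unit relative density,
#'   mm^-1 (water-like megavoltage scale by default).
#' @return A `beam_spec`.
#' @export
beam_spec <- function(isocenter = c(0, 0, 0), direction = c(0, 1, 0),
                      field_size = c(50, 50), sad = 1000, weight = 1,
                      mu = 0.005) {
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("beam direction must be non-zero")
  if (any(field_size <= 0)) stop("field size must be positive")
  if (weight < 0) stop("beam weight must be >= 0")
  structure(list(isocenter = as.double(isocenter),
                 direction = as.double(direction) / nrm,
                 field_size = rep_len(as.double(field_size), 2L),
                 sad = sad, weight = weight, mu = mu),
            class = "beam_spec")
}

#' Dose grid wrapper
#'
#' A [scalar_grid()] in Gy with provenance bookkeeping.
#'
#' @param grid `scalar_grid` of non-negative values.
#' @param provenance `"phase"`, `"daily"` or `"cumulative"`.
#' @param fraction_ids integer ids of the fractions included.
#' @return A `dose_grid` (also a `scalar_grid`).
#' @export
dose_grid <- function(grid, provenance = c("phase", "daily", "cumulative"),
                      fraction_ids = integer()) {
  provenance <- match.arg(provenance)
  if (min(grid$values) < 0) stop("dose values must be >= 0")
  grid$unit_tag <- "Gy"
  grid$provenance <- provenance
  grid$fraction_ids <- as.integer(fraction_ids)
  class(grid) <- unique(c("dose_grid", class(grid)))
  grid
}

# orthonormal basis perpendicular to the beam axis
beam_basis <- function(axis) {
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

#' Compute dose on an image with the stand-in engine
#'
#' For each voxel inside a beam's divergent rectangular aperture the
#' contribution is `weight * exp(-mu * radiological_path) * (SAD / d)^2`,
#' where the radiological path is the line integral of relative density
#' `max((HU + 1000) / 1000, 0)` from the source, evaluated by ray marching,
#' and `d` is the source--voxel distance. Contributions are summed over
#' beams. This is an exponential-attenuation model without scatter or
#' build-up, not a clinical dose calculation.
#'
#' @param image HU [scalar_grid()].
#' @param beams list of [beam_spec()]s (non-empty).
#' @param step_mm ray-marching step length, mm.
#' @param output_scale multiplies the summed contributions (sets Gy scale).
#' @return A [dose_grid()] with provenance `"phase"`.
#' @export
compute_dose <- function(image, beams, step_mm = NULL, output_scale = 1) {
  if (inherits(beams, "beam_spec")) beams <- list(beams)
  if (length(beams) == 0) stop("at least one beam is required")
  g <- geometry_of(image)
  if (is.null(step_mm)) step_mm <- min(g$spacing)
  pts <- voxel_centers(g)
  lo <- g$origin - g$spacing / 2
  hi <- g$origin + (g$size - 0.5) * g$spacing
  density <- pmax((image$values + 1000) / 1000, 0)
  total <- numeric(nrow(pts))

  for (bm in beams) {
    src <- bm$isocenter - bm$sad * bm$direction
    if (all(src >= lo & src <= hi))
      stop("beam source lies inside the image volume")
    if (bm$weight == 0) next
    vec <- sweep(pts, 2L, src, `-`)
    t_ax <- vec %*% bm$direction
    basis <- beam_basis(bm$direction)
    u1 <- (vec %*% basis$e1) * bm$sad / t_ax
    u2 <- (vec %*% basis$e2) * bm$sad / t_ax
    inside <- t_ax > 0 & abs(u1) <= bm$field_size[1] / 2 &
              abs(u2) <= bm$field_size[2] / 2
    idx <- which(inside)
    if (length(idx) == 0) next
    v <- vec[idx, , drop = FALSE]
    d <- sqrt(rowSums(v^2))
    # param u in [0,1] along source -> voxel; find entry into the grid box
    u_in <- rep(0, length(idx))
    for (a in 1:3) {
      da <- v[, a]
      nz <- abs(da) > 1e-12
      ua <- pmin((lo[a] - src[a]) / da[nz], (hi[a] - src[a]) / da[nz])
      u_in[nz] <- pmax(u_in[nz], ua)
    }
    u_in <- pmin(pmax(u_in, 0), 1)
    seg <- d * (1 - u_in)
    n_steps <- max(2L, ceiling(max(seg) / step_mm))
    radpath <- numeric(length(idx))
    for (k in seq_len(n_steps)) {
      uu <- u_in + (1 - u_in) * (k - 0.5) / n_steps
      p <- sweep(v * uu, 2L, src, `+`)
      radpath <- radpath +
        interp_trilinear(density, g, p, fill = 0) * seg / n_steps
    }
    total[idx] <- total[idx] +
      bm$weight * exp(-bm$mu * radpath) * (bm$sad / d)^2
  }
  dose_grid(scalar_grid(array(total * output_scale, g$size), g$origin,
                        g$spacing, unit_tag = "Gy"),
            provenance = "phase")
}

#' Warp a dose grid through a displacement field
#'
#' Trilinear pull-sampling of the dose at `x + d(x)`; voxels mapping outside
#' the source dose grid receive 0 Gy. Direct interpolation-based warping (no
#' mass/energy-transfer correction). Warping with a `NULL` field on the same
#' geometry is exact.
#'
#' @param dose a [dose_grid()] (or Gy `scalar_grid`).
#' @param dvf [vector_field()] on the target geometry, or `NULL` for
#'   identity.
#' @return A [dose_grid()] on the field geometry.
#' @export
warp_dose <- function(dose, dvf = NULL) {
  if (is.null(dvf)) {
    return(dose_grid(scalar_grid(dose$values, dose$origin, dose$spacing,
                                 unit_tag = "Gy"),
                     provenance = dose$provenance %||% "phase",
                     fraction_ids = dose$fraction_ids %||% integer()))
  }
  out <- warp_image(dose, dvf, fill = 0)
  out$values[out$values < 0] <- 0
  dose_grid(out, provenance = dose$provenance %||% "phase",
            fraction_ids = dose$fraction_ids %||% integer())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Accumulate per-phase doses onto the reference phase
#'
#' Computes `sum_p w_p * warp(D_p, dvf_p)`: each phase dose is pulled onto
#' the reference-phase grid through its reference-to-phase field and the
#' weighted sum taken. Uniform weights 1/10 correspond to equal time spent
#' per sorted phase.
#'
#' @param phase_doses list of [dose_grid()]s (one per phase).
#' @param phase_dvfs list of [vector_field()]s on the reference geometry
#'   (reference -> phase); `NULL` entries mean identity.
#' @param weights phase weights summing to 1.
#' @return A [dose_grid()] with provenance `"daily"`.
#' @export
accumulate_4d <- function(phase_doses, phase_dvfs = NULL,
                          weights = rep(1 / length(phase_doses),
                                        length(phase_doses))) {
  n <- length(phase_doses)
  if (!is.null(phase_dvfs) && length(phase_dvfs) != n)
    stop("need one DVF (or NULL) per phase dose")
  if (abs(sum(weights) - 1) > 1e-6)
    stop("phase weights must sum to 1 (got ", sum(weights), ")")
  acc <- NULL
  for (p in seq_len(n)) {
    w <- warp_dose(phase_doses[[p]],
                   if (is.null(phase_dvfs)) NULL else phase_dvfs[[p]])
    acc <- if (is.null(acc)) weights[p] * w$values else
      acc + weights[p] * w$values
  }
  ref <- if (!is.null(phase_dvfs) && !is.null(phase_dvfs[[1]]))
    geometry_of(phase_dvfs[[1]]) else geometry_of(phase_doses[[1]])
  dose_grid(scalar_grid(acc, ref$origin, ref$spacing, unit_tag = "Gy"),
            provenance = "daily")
}

#' Replan chain
#'
#' Ordered sequence of planning CTs. Each entry after the first carries the
#' pull field on the *previous* plan's geometry that maps it into the newer
#' plan's frame, so a dose on plan `k` is pulled back to plan `k-1` by
#' warping with `dvf_to_prev[[k]]`, and stepwise back to the pretreatment CT.
#'
#' @param plan_ids character plan identifiers (first = pretreatment CT).
#' @param start_dates `Date` vector, strictly increasing; plan `k` governs
#'   fractions dated in `[start_dates[k], start_dates[k+1])`.
#' @param dvf_to_prev list of [vector_field()]s (entry 1 is `NULL`).
#' @return A `plan_chain`.
#' @export
plan_chain <- function(plan_ids, start_dates, dvf_to_prev = NULL) {
  n <- length(plan_ids)
  start_dates <- as.Date(start_dates)
  if (length(start_dates) != n) stop("one start date per plan required")
  if (n > 1 && any(diff(start_dates) <= 0))
    stop("plan start dates must be strictly increasing")
  if (is.null(dvf_to_prev)) dvf_to_prev <- vector("list", n)
  if (length(dvf_to_prev) != n) stop("one dvf_to_prev entry per plan required")
  if (n > 1) for (k in 2:n) if (is.null(dvf_to_prev[[k]]))
    stop("plan ", k, " is missing its DVF to the previous plan")
  structure(list(plan_ids = plan_ids, start_dates = start_dates,
                 dvf_to_prev = dvf_to_prev), class = "plan_chain")
}

#' Accumulate daily doses over a course, through the replan chain
#'
#' Each daily dose (on the geometry of the plan in effect on its date) is
#' warped stepwise to the nearest earlier replan CT and onward to the
#' pretreatment CT, then all warped dailies are summed. With a single plan
#' and identity warps this reduces to plain summation.
#'
#' @param daily_doses list of [dose_grid()]s.
#' @param dates `Date` vector, one per daily dose.
#' @param chain a [plan_chain()] (defaults to a trivial single-plan chain).
#' @return A [dose_grid()] with provenance `"cumulative"` on the
#'   pretreatment-CT geometry.
#' @export
accumulate_course <- function(daily_doses, dates = NULL, chain = NULL) {
  n <- length(daily_doses)
  if (n == 0) stop("no daily doses supplied")
  if (is.null(chain))
    chain <- plan_chain("plan", if (is.null(dates)) Sys.Date() else min(dates))
  if (is.null(dates)) dates <- rep(chain$start_dates[1], n)
  dates <- as.Date(dates)
  acc <- NULL
  for (f in seq_len(n)) {
    if (dates[f] < chain$start_dates[1])
      stop("fraction ", f, " (", dates[f], ") predates the first plan (",
           chain$start_dates[1], ")")
    seg <- max(which(chain$start_dates <= dates[f]))
    d <- daily_doses[[f]]
    while (seg > 1) {
      d <- warp_dose(d, chain$dvf_to_prev[[seg]])
      seg <- seg - 1
    }
    acc <- if (is.null(acc)) d$values else acc + d$values
  }
  ref <- geometry_of(daily_doses[[1]])
  if (!is.null(chain$dvf_to_prev[[length(chain$dvf_to_prev)]]))
    ref <- geometry_of(chain$dvf_to_prev[[2]])
  dose_grid(scalar_grid(acc, ref$origin, ref$spacing, unit_tag = "Gy"),
            provenance = "cumulative", fraction_ids = seq_len(n))
}

#' Integral dose (sum of dose times voxel volume)
#'
#' @param dose a [dose_grid()].
#' @return scalar, Gy * mm^3.
#' @export
integral_dose <- function(dose) sum(dose$values) * prod(dose$spacing)
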