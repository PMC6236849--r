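# Registration commissioning and patient-specific QA: target registration
# error against landmark pairs, contour agreement (DICE, mean surface
# distance, volume/centre-of-mass flags), and DVH metrics with
# percent-of-plan deltas.

#' Target registration error of a displacement field
#'
#' For each landmark pair the error is the distance between the true moving
#' position and the fixed position displaced by the field,
#' `|p_moving - (p_fixed + d(p_fixed))|`; with no field it is the raw pair
#' distance (the pre-registration separation). Multiple landmark sets are
#' pooled per-landmark, the reporting convention of public lung-landmark
#' benchmarks; per-set summaries are also returned.
#'
#' @param landmarks a [landmark_set()] or list of them.
#' @param dvf a [vector_field()] on the fixed-image geometry, or `NULL`.
#' @return A `tre_report`: list with `errors_mm` (pooled), `mean_mm`,
#'   `sd_mm`, `n`, and `per_set` tibble (set, n, mean_mm, sd_mm).
#' @export
compute_tre <- function(landmarks, dvf = NULL) {
  if (inherits(landmarks, "landmark_set")) landmarks <- list(landmarks)
  per_set <- vector("list", length(landmarks))
  pooled <- numeric(0)
  for (i in seq_along(landmarks)) {
    lm <- landmarks[[i]]
    mapped <- lm$points_fixed
    if (!is.null(dvf)) mapped <- mapped + sample_vector(dvf, lm$points_fixed)
    err <- sqrt(rowSums((lm$points_moving - mapped)^2))
    pooled <- c(pooled, err)
    per_set[[i]] <- tibble::tibble(set = i, n = length(err),
                                   mean_mm = mean(err),
                                   sd_mm = if (length(err) > 1) stats::sd(err) else 0)
  }
  structure(list(errors_mm = pooled, mean_mm = mean(pooled),
                 sd_mm = if (length(pooled) > 1) stats::sd(pooled) else 0,
                 n = length(pooled), per_set = dplyr::bind_rows(per_set)),
            class = "tre_report")
}

#' @export
print.tre_report <- function(x, ...) {
  cat(sprintf("<tre_report> %d landmarks, TRE %.2f +/- %.2f mm\n",
              x$n, x$mean_mm, x$sd_mm))
  invisible(x)
}

# surface voxels: in-mask voxels with at least one 6-neighbour outside
surface_voxels <- function(mask) {
  m <- mask > 0.5
  inner <- m
  for (a in 1:3) {
    inner <- inner & shift_array(m, replace(c(0L, 0L, 0L), a, 1L)) &
                     shift_array(m, replace(c(0L, 0L, 0L), a, -1L))
  }
  which(m & !inner)
}

min_dists <- function(pa, pb) {
  # nearest-neighbour distances from each row of pa to the set pb, blockwise
  out <- numeric(nrow(pa))
  bs <- 2000L
  b2 <- rowSums(pb^2)
  for (s in seq(1, nrow(pa), by = bs)) {
    e <- min(s + bs - 1L, nrow(pa))
    blk <- pa[s:e, , drop = FALSE]
    d2 <- outer(rowSums(blk^2), b2, `+`) - 2 * blk %*% t(pb)
    out[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Contour agreement metrics between two masks
#'
#' DICE overlap, symmetric mean surface distance (average of the two
#' directed mean nearest-surface-voxel distances), relative volume change
#' `(|B| - |A|) / |A|`, and centre-of-mass shift. Flags trip *strictly above*
#' the empirical QA thresholds: 10% volume change and 3 mm COM translation.
#'
#' @param mask_a,mask_b [roi_mask()]s on the same geometry (A = reference,
#'   e.g. planned contour; B = comparison, e.g. propagated contour).
#' @param volume_threshold,com_threshold_mm flag thresholds.
#' @return A `contour_qa` tibble row: `dice`, `msd_mm`, `volume_change`,
#'   `com_shift_mm`, `volume_flag`, `com_flag`.
#' @export
contour_metrics <- function(mask_a, mask_b, volume_threshold = 0.10,
                            com_threshold_mm = 3) {
  if (!same_geometry(mask_a$grid, mask_b$grid))
    stop("masks must share one geometry")
  g <- geometry_of(mask_a$grid)
  a <- mask_a$grid$values > 0.5
  b <- mask_b$grid$values > 0.5
  na <- sum(a); nb <- sum(b)
  if (na == 0 && nb == 0) stop("both masks are empty")
  dice <- 2 * sum(a & b) / (na + nb)
  pts <- voxel_centers(g)
  sa <- surface_voxels(mask_a$grid$values)
  sb <- surface_voxels(mask_b$grid$values)
  msd <- if (length(sa) && length(sb)) {
    (mean(min_dists(pts[sa, , drop = FALSE], pts[sb, , drop = FALSE])) +
     mean(min_dists(pts[sb, , drop = FALSE], pts[sa, , drop = FALSE]))) / 2
  } else NA_real_
  volume_change <- (nb - na) / na
  com_a <- colMeans(pts[a, , drop = FALSE])
  com_b <- colMeans(pts[b, , drop = FALSE])
  com_shift <- sqrt(sum((com_b - com_a)^2))
  out <- tibble::tibble(
    dice = dice, msd_mm = msd, volume_change = volume_change,
    com_shift_mm = com_shift,
    volume_flag = abs(volume_change) > volume_threshold,
    com_flag = com_shift > com_threshold_mm)
  class(out) <- c("contour_qa", class(out))
  out
}

#' DVH metrics of a dose within an ROI
#'
#' `D_q` is the dose level received by at least `q`% of the ROI volume: the
#' ROI voxel doses are sorted in decreasing order and the cumulative
#' dose-volume curve is interpolated linearly at volume fraction `q`/100.
#' `V_x` is the percentage of ROI voxels receiving at least `x` Gy. When a
#' plan dose is supplied, each metric also gets `percent` (Tx as % of plan)
#' and `delta_percent` (`(Tx - plan) / plan * 100`).
#'
#' @param dose a [dose_grid()].
#' @param roi an [roi_mask()] on the dose geometry.
#' @param plan_dose optional plan [dose_grid()] for percent-of-plan columns.
#' @param d_levels volume percentages for D metrics.
#' @param v_levels_gy dose levels (Gy) for V metrics.
#' @return A tibble (class `dvh_metrics`): `metric`, `value` plus `plan`,
#'   `percent`, `delta_percent` when a plan dose is given.
#' @export
dvh_metrics <- function(dose, roi, plan_dose = NULL,
                        d_levels = c(99, 95, 90), v_levels_gy = 20) {
  if (!same_geometry(dose, roi$grid)) stop("dose and ROI geometries differ")
  sel <- roi$grid$values > 0.5
  if (!any(sel)) stop("ROI '", roi$name, "' is empty")
  vals <- dose$values[sel]
  one <- function(v) {
    s <- sort(v, decreasing = TRUE)
    n <- length(s)
    dq <- function(q) {
      if (n == 1) return(s)
      stats::approx(x = (seq_len(n)) / n, y = s, xout = q / 100,
                    rule = 2)$y
    }
    c(stats::setNames(vapply(d_levels, dq, 0), paste0("D", d_levels)),
      stats::setNames(vapply(v_levels_gy, function(x) 100 * mean(v >= x), 0),
                      paste0("V", v_levels_gy)),
      max = max(v), mean = mean(v))
  }
  m <- one(vals)
  out <- tibble::tibble(metric = names(m), value = unname(m))
  if (!is.null(plan_dose)) {
    if (!same_geometry(plan_dose, roi$grid))
      stop("plan dose and ROI geometries differ")
    mp <- one(plan_dose$values[sel])
    out$plan <- unname(mp)
    out$percent <- ifelse(out$plan > 0, out$value / out$plan * 100, NA_real_)
    out$delta_percent <- ifelse(out$plan > 0,
                                (out$value - out$plan) / out$plan * 100,
                                NA_real_)
  }
  class(out) <- c("dvh_metrics", class(out))
  attr(out, "roi") <- roi$name
  out
}

#' Full dose--volume histogram curve
#'
#' @param dose a [dose_grid()].
#' @param roi an [roi_mask()].
#' @param n_bins number of dose bins.
#' @return tibble with `dose_gy` and `volume_percent` (cumulative, % of ROI
#'   receiving at least that dose).
#' @export
dvh_curve <- function(dose, roi, n_bins = 200) {
  sel <- roi$grid$values > 0.5
  if (!any(sel)) stop("ROI '", roi$name, "' is empty")
  v <- dose$values[sel]
  edges <- seq(0, max(v) * 1.02 + 1e-9, length.out = n_bins)
  tibble::tibble(roi = roi$name, dose_gy = edges,
                 volume_percent = vapply(edges, function(e) 100 * mean(v >= e), 0))
}

#' Per-fraction and cumulative DVH report for a course
#'
#' @param plan_dose plan [dose_grid()] on the reference geometry.
#' @param daily_doses list of daily [dose_grid()]s on the same geometry.
#' @param cumulative_dose cumulative [dose_grid()]; `NULL` to sum the
#'   dailies.
#' @param rois named list of [roi_mask()]s (may be empty).
#' @param prescription_gy optional prescribed dose for context columns.
#' @return A tibble (class `course_report`): `fraction` (`"plan"`, `"1"`,
#'   ..., `"cumulative"`), `roi`, `metric`, `value`, `plan`, `percent`,
#'   `delta_percent`, ordered deterministically.
#' @export
course_report <- function(plan_dose, daily_doses, cumulative_dose = NULL,
                          rois = list(), prescription_gy = NULL) {
  if (is.null(cumulative_dose) && length(daily_doses)) {
    acc <- Reduce(`+`, lapply(daily_doses, function(d) d$values))
    cumulative_dose <- dose_grid(
      scalar_grid(acc, plan_dose$origin, plan_dose$spacing, unit_tag = "Gy"),
      provenance = "cumulative")
  }
  rows <- list()
  for (rn in names(rois)) {
    roi <- rois[[rn]]
    add <- function(tag, dose, ref) {
      m <- dvh_metrics(dose, roi, plan_dose = ref)
      m$fraction <- tag; m$roi <- rn
      rows[[length(rows) + 1]] <<- m
    }
    add("plan", plan_dose, plan_dose)
    for (f in seq_along(daily_doses))
      add(as.character(f), daily_doses[[f]], NULL)
    if (!is.null(cumulative_dose)) add("cumulative", cumulative_dose, plan_dose)
  }
  out <- if (length(rows)) {
    dplyr::select(dplyr::bind_rows(rows), dplyr::all_of(c("fraction", "roi", "metric", "value")),
                  dplyr::any_of(c("plan", "percent", "delta_percent")))
  } else {
    tibble::tibble(fraction = character(), roi = character(),
                   metric = character(), value = numeric(),
                   plan = numeric(), percent = numeric(),
                   delta_percent = numeric())
  }
  class(out) <- c("course_report", class(out))
  attr(out, "prescription_gy") <- prescription_gy
  out
}
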