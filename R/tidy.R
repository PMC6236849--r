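# broom-style tidiers for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.tre_report <- function(x, ...) {
  tibble::tibble(landmark = seq_len(x$n), error_mm = x$errors_mm)
}

#' @export
glance.tre_report <- function(x, ...) {
  tibble::tibble(n = x$n, mean_mm = x$mean_mm, sd_mm = x$sd_mm,
                 max_mm = max(x$errors_mm))
}

#' @export
tidy.vector_field <- function(x, ...) {
  pts <- voxel_centers(x)
  tibble::tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                 dx = as.vector(x$dx), dy = as.vector(x$dy),
                 dz = as.vector(x$dz))
}

#' @export
glance.vector_field <- function(x, ...) {
  mag <- sqrt(x$dx^2 + x$dy^2 + x$dz^2)
  tibble::tibble(domain = x$domain, codomain = x$codomain,
                 n_voxels = prod(x$size), mean_mm = mean(mag),
                 max_mm = max(mag))
}

#' @export
tidy.scalar_grid <- function(x, ...) {
  pts <- voxel_centers(x)
  tibble::tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                 value = as.vector(x$values))
}

#' @export
glance.scalar_grid <- function(x, ...) {
  tibble::tibble(unit = x$unit_tag, n_voxels = prod(x$size),
                 min = min(x$values), mean = mean(x$values),
                 max = max(x$values))
}

#' @export
glance.dose_grid <- function(x, ...) {
  tibble::tibble(provenance = x$provenance, n_fractions = length(x$fraction_ids),
                 max_gy = max(x$values), mean_gy = mean(x$values),
                 integral_gy_mm3 = integral_dose(x))
}

#' @export
tidy.landmark_set <- function(x, ...) {
  tibble::tibble(landmark = seq_len(x$n),
                 fx = x$points_fixed[, 1], fy = x$points_fixed[, 2],
                 fz = x$points_fixed[, 3],
                 mx = x$points_moving[, 1], my = x$points_moving[, 2],
                 mz = x$points_moving[, 3],
                 distance_mm = sqrt(rowSums((x$points_fixed - x$points_moving)^2)))
}
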