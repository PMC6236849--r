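# ggplot2 visualisation helpers.

#' Plot an axial/coronal/sagittal slice of a grid
#'
#' @param grid a [scalar_grid()] (or [dose_grid()]).
#' @param plane `"axial"` (xy), `"coronal"` (xz) or `"sagittal"` (yz).
#' @param index 1-based slice index along the remaining axis (middle by
#'   default).
#' @return a ggplot.
#' @export
plot_slice <- function(grid, plane = c("axial", "coronal", "sagittal"),
                       index = NULL) {
  plane <- match.arg(plane)
  ax <- switch(plane, axial = 3L, coronal = 2L, sagittal = 1L)
  keep <- setdiff(1:3, ax)
  if (is.null(index)) index <- ceiling(grid$size[ax] / 2)
  sl <- switch(plane,
               axial = grid$values[, , index],
               coronal = grid$values[, index, ],
               sagittal = grid$values[index, , ])
  co <- axis_coords(grid)
  df <- expand.grid(h = co[[keep[1]]], v = co[[keep[2]]])
  df$value <- as.vector(sl)
  lab <- c("x (mm)", "y (mm)", "z (mm)")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$h, y = .data$v,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = grid$unit_tag) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = lab[keep[1]], y = lab[keep[2]],
                  title = sprintf("%s slice %d", plane, index)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.scalar_grid <- function(object, ...) plot_slice(object, ...)

#' DVH plot for one or more dose/ROI combinations
#'
#' @param doses named list of [dose_grid()]s (e.g. plan vs reconstructed).
#' @param rois named list of [roi_mask()]s.
#' @return a ggplot of cumulative DVH curves.
#' @export
plot_dvh <- function(doses, rois) {
  if (inherits(doses, "scalar_grid")) doses <- list(dose = doses)
  if (inherits(rois, "roi_mask")) rois <- stats::setNames(list(rois), rois$name)
  curves <- purrr::map_dfr(names(doses), function(dn)
    purrr::map_dfr(names(rois), function(rn)
      dplyr::mutate(dvh_curve(doses[[dn]], rois[[rn]]), dose_name = dn)))
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$dose_gy, y = .data$volume_percent,
                               colour = .data$roi, linetype = .data$dose_name)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Dose (Gy)", y = "Volume (%)",
                  colour = "ROI", linetype = "Dose") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.tre_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$error_mm)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = object$mean_mm, linetype = 2) +
    ggplot2::labs(x = "Target registration error (mm)", y = "Landmarks",
                  title = sprintf("TRE %.2f +/- %.2f mm (n = %d)",
                                  object$mean_mm, object$sd_mm, object$n)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.phase_pairing <- function(object, ...) {
  long <- tidyr::pivot_longer(object,
                              c("d_cbct_mm", "d_ct_mm"),
                              names_to = "series", values_to = "position")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cbct_phase,
                                     y = .data$position,
                                     colour = .data$series)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "CBCT phase", y = "Diaphragm SI position (mm)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
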