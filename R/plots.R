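#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a density-radius sweep
#'
#' Object count against density calculation radius; plateaus (stable
#' stretches) mark the segmentation scales.
#'
#' @param object A `radius_sweep` from [sweep_radii()].
#' @param plateaus Optional plateau table from [detect_plateaus()], drawn
#'   as vertical lines.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.radius_sweep <- function(object, plateaus = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$radius_nm,
                                    y = .data$n_objects)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "density radius (nm)", y = "number of objects") +
    ggplot2::theme_minimal()
  if (!is.null(plateaus) && nrow(plateaus) > 0)
    p <- p + ggplot2::geom_vline(data = plateaus,
                                 ggplot2::aes(xintercept = .data$radius_nm),
                                 linetype = "dashed", color = "darkgreen")
  p
}

#' Plot a fiber-radius histogram
#'
#' @param object A `thickness_result` from [local_thickness()].
#' @param ... Unused.
#' @return A ggplot with the modal radius marked.
#' @export
autoplot.thickness_result <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = .data$mid_nm, y = .data$count)) +
    ggplot2::geom_col(width = object$bin_width * 0.92, fill = "steelblue") +
    ggplot2::geom_vline(xintercept = object$modal_radius_nm,
                        linetype = "dashed") +
    ggplot2::labs(x = "local fiber radius (nm)", y = "skeleton voxels",
                  subtitle = sprintf("mode %.1f nm (SD %.1f, n = %d)",
                                     object$modal_radius_nm, object$sd_nm,
                                     object$n)) +
    ggplot2::theme_minimal()
}

#' Plot a Fourier shell correlation curve
#'
#' @param object An `fsc_curve` from [fsc_curve()].
#' @param criterion Criterion line to draw (default 0.143).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fsc_curve <- function(object, criterion = 0.143, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$freq_per_nm, y = .data$fsc)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = criterion, linetype = "dashed") +
    ggplot2::labs(x = "spatial frequency (1/nm)", y = "FSC") +
    ggplot2::theme_minimal()
}
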