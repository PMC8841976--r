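#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a thickness result
#'
#' One row per skeleton voxel with its local radius and whether it was
#' excluded by the slab-border rule.
#'
#' @param x A `thickness_result` from [local_thickness()].
#' @param ... Unused.
#' @return A tibble with columns `z`, `y`, `x`, `radius_nm`, `excluded`.
#' @export
tidy.thickness_result <- function(x, ...) x$radii

#' One-row summary of a thickness result
#'
#' @param x A `thickness_result`.
#' @param ... Unused.
#' @return A tibble: `modal_radius_nm`, `sd_nm`, `se_nm`, `n`,
#'   `diameter_nm`, `segmentation_radius_nm`.
#' @export
glance.thickness_result <- function(x, ...) {
  tibble::tibble(modal_radius_nm = x$modal_radius_nm, sd_nm = x$sd_nm,
                 se_nm = x$se_nm, n = x$n,
                 diameter_nm = 2 * x$modal_radius_nm,
                 segmentation_radius_nm =
                   if (is.null(x$segmentation_radius_nm)) NA_real_
                   else x$segmentation_radius_nm)
}

#' Tidy a pipeline run report
#'
#' @param x A `run_report` from [run_pipeline()].
#' @param ... Unused.
#' @return The summary table (one row per plateau).
#' @export
tidy.run_report <- function(x, ...) x$summary

#' One-row summary of a pipeline run
#'
#' @param x A `run_report`.
#' @param ... Unused.
#' @return A tibble with particle and plateau counts, the first-plateau
#'   modal radius and the run time.
#' @export
glance.run_report <- function(x, ...) {
  tibble::tibble(n_particles = x$counts$n_particles,
                 n_plateaus = x$counts$n_plateaus,
                 modal_radius_nm = x$summary$modal_radius_nm[1],
                 diameter_nm = x$summary$diameter_nm[1],
                 elapsed_s = x$timings)
}
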