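#' Configuration for an end-to-end analysis run
#'
#' Bundles every knob of the tomogram-to-thickness pipeline. Exactly one
#' input source must be given: a phantom spec, a volume (in memory or a
#' MRC/TIFF file path), or a particle table (in memory or a CSV path).
#'
#' @param phantom_spec A [phantom_spec()] to generate input from.
#' @param volume A [vol3d()], or `volume_file` an MRC/TIFF path.
#' @param volume_file Path to an MRC or multi-page TIFF volume.
#' @param particles A `particle_set`, or `particle_csv` a CSV path.
#' @param particle_csv Path to a particle CSV (`id, z_nm, y_nm, x_nm`).
#' @param voxel_size Voxel size in nm, required for TIFF or CSV input.
#' @param invert Invert volume contrast on load (TEM-dark particles).
#' @param threshold_method `"isodata"` (default) or `"otsu"`.
#' @param connectivity Particle labeling connectivity (default 26).
#' @param min_voxels Minimum particle size in voxels (default 2).
#' @param k Density neighbor count (default 40).
#' @param sweep_min,sweep_max,sweep_step Density radius sweep in nm
#'   (default 20-200 nm step 10, bracketing the 100-200 nm fiber range).
#' @param plateau_rel_tol,plateau_min_span Plateau rule, see
#'   [detect_plateaus()].
#' @param bin_width Radius histogram bin width in nm (default 5).
#' @param border_exclude Exclude z-face-truncated skeleton voxels
#'   (default TRUE).
#' @param decimate Density grid decimation factor (default 1).
#' @param seg_rule How the segmentation radius is chosen inside each
#'   plateau: `"sufficiency"` (default) clamps the particle set's
#'   [knn_radius()] — the scale at which neighbor counts saturate `k`, so
#'   the thresholded boundary is statistically resolved — into the
#'   plateau's radius range; `"onset"` and `"midpoint"` use those plateau
#'   radii directly.
#' @param prune_len Skeleton branch pruning for thickness measurement:
#'   `"adaptive"` (default) or an integer, see [local_thickness()].
#' @param phantom_particles For phantom input, run the density stages on
#'   the phantom's ground-truth particle centroids (`"true"`, default) or
#'   on particles re-detected from the rendered volume (`"detected"`).
#' @param fsc Compute an even/odd FSC (phantom input only).
#' @param fsc_criterion FSC threshold (default 0.143).
#' @param out_dir Output directory; `NULL` keeps everything in memory.
#' @param seed Master seed for the run.
#' @param quiet Suppress progress messages (default TRUE).
#' @return A `run_config` list.
#' @export
run_config <- function(phantom_spec = NULL, volume = NULL, volume_file = NULL,
                       particles = NULL, particle_csv = NULL,
                       voxel_size = NULL, invert = FALSE,
                       threshold_method = "isodata", connectivity = 26L,
                       min_voxels = 2L, k = 40L,
                       sweep_min = 20, sweep_max = 200, sweep_step = 10,
                       plateau_rel_tol = 0.05, plateau_min_span = 3L,
                       bin_width = 5, border_exclude = TRUE, decimate = 1L,
                       seg_rule = c("sufficiency", "onset", "midpoint"),
                       prune_len = "adaptive",
                       phantom_particles = c("true", "detected"),
                       fsc = FALSE, fsc_criterion = 0.143,
                       out_dir = NULL, seed = 1L, quiet = TRUE) {
  seg_rule <- match.arg(seg_rule)
  phantom_particles <- match.arg(phantom_particles)
  n_inputs <- sum(!is.null(phantom_spec), !is.null(volume),
                  !is.null(volume_file), !is.null(particles),
                  !is.null(particle_csv))
  if (n_inputs != 1L)
    stop("exactly one input source must be given", call. = FALSE)
  if (sweep_min >= sweep_max || sweep_step <= 0 || sweep_min <= 0)
    stop("sweep must satisfy 0 < min < max with step > 0", call. = FALSE)
  if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  if (fsc_criterion <= 0 || fsc_criterion >= 1)
    stop("`fsc_criterion` must lie in (0, 1)", call. = FALSE)
  cfg <- list(phantom_spec = phantom_spec, volume = volume,
              volume_file = volume_file, particles = particles,
              particle_csv = particle_csv, voxel_size = voxel_size,
              invert = invert, threshold_method = threshold_method,
              connectivity = as.integer(connectivity),
              min_voxels = as.integer(min_voxels), k = as.integer(k),
              sweep_min = sweep_min, sweep_max = sweep_max,
              sweep_step = sweep_step, plateau_rel_tol = plateau_rel_tol,
              plateau_min_span = as.integer(plateau_min_span),
              bin_width = bin_width, border_exclude = border_exclude,
              decimate = as.integer(decimate), seg_rule = seg_rule,
              prune_len = prune_len, phantom_particles = phantom_particles,
              fsc = fsc,
              fsc_criterion = fsc_criterion, out_dir = out_dir,
              seed = as.integer(seed), quiet = quiet)
  class(cfg) <- "run_config"
  cfg
}

config_flat <- function(cfg) {
  # scalar view of the config used for hashing and persistence
  flat <- cfg[vapply(cfg, function(v) is.atomic(v) && length(v) >= 1,
                     logical(1))]
  if (!is.null(cfg$phantom_spec)) {
    sp <- unclass(cfg$phantom_spec)
    names(sp) <- paste0("phantom.", names(sp))
    flat <- c(flat, sp[vapply(sp, is.atomic, logical(1))])
  }
  flat[order(names(flat))]
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".cfg")
  on.exit(unlink(tmp))
  write_config(config_flat(cfg), tmp)
  unname(tools::md5sum(tmp))
}

stage <- function(name, quiet, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(expr), error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  if (!quiet)
    message(sprintf("[%s] done in %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full fiber-thickness pipeline
#'
#' Executes, in order: input loading (or phantom generation), particle
#' detection, density-radius sweep, plateau detection, per-plateau fiber
#' segmentation and local-thickness measurement, and (optionally, for
#' phantom input) even/odd FSC. Every intermediate is persisted when
#' `out_dir` is set; rerunning with the same config and seed reproduces
#' all numeric outputs bit-identically.
#'
#' @param config A [run_config()].
#' @return A `run_report`: list with `config_hash`, `seed`, `versions`,
#'   `counts` (per-stage sizes), `sweep`, `plateaus`, `thickness` (list of
#'   `thickness_result`), `summary` (the [radius_report()] table),
#'   optional `fsc`, and `timings`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  q <- isTRUE(config$quiet)
  out <- config$out_dir
  if (!is.null(out)) dir.create(out, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  set.seed(config$seed)
  t_start <- proc.time()[["elapsed"]]
  counts <- list()
  ph <- NULL

  # ---- input
  if (!is.null(config$phantom_spec)) {
    ph <- stage("phantom", q, decorate_and_render(config$phantom_spec))
    if (!is.null(out)) write_phantom(ph, file.path(out, "phantom"))
    vol <- if (config$phantom_particles == "detected") ph$volume else NULL
  } else if (!is.null(config$volume) || !is.null(config$volume_file)) {
    vol <- stage("load", q, {
      if (!is.null(config$volume)) config$volume
      else if (grepl("\\.mrc$", config$volume_file, ignore.case = TRUE))
        read_mrc(config$volume_file)
      else read_tiff_stack(config$volume_file, config$voxel_size)
    })
    if (config$invert) vol$data <- max(vol$data) - vol$data
  } else {
    vol <- NULL
  }

  # ---- particles
  if (!is.null(vol)) {
    particles <- stage("detect", q, {
      b <- binarize(vol, method = config$threshold_method)
      if (!is.null(out)) {
        m <- b$mask
        write_mrc(vol3d(array(as.numeric(m$data), dim(m$data)),
                        m$voxel_size, m$origin),
                  file.path(out, "binary_mask.mrc"))
      }
      label_particles(b$mask, connectivity = config$connectivity,
                      min_voxels = config$min_voxels)
    })
  } else if (!is.null(ph)) {
    particles <- ph$particles
  } else if (!is.null(config$particles)) {
    particles <- config$particles
  } else {
    particles <- stage("load-particles", q,
                       read_particles_csv(config$particle_csv,
                                          voxel_size = config$voxel_size))
  }
  counts$n_particles <- nrow(particles)
  if (!is.null(out))
    write_particles_csv(particles, file.path(out, "particles.csv"))

  # ---- sweep + plateaus
  radii <- seq(config$sweep_min, config$sweep_max, by = config$sweep_step)
  sweep_tab <- stage("sweep", q,
                     sweep_radii(particles, radii, k = config$k,
                                 decimate = config$decimate))
  if (!is.null(out)) {
    readr::write_csv(tibble::as_tibble(sweep_tab)[, c("radius_nm",
                                                      "n_objects")],
                     file.path(out, "sweep.csv"))
    try(suppressMessages(ggplot2::ggsave(file.path(out, "sweep.png"),
                                         autoplot.radius_sweep(sweep_tab),
                                         width = 5, height = 4, dpi = 120)),
        silent = TRUE)
  }
  plateaus <- stage("plateaus", q,
                    detect_plateaus(sweep_tab,
                                    rel_tol = config$plateau_rel_tol,
                                    min_span = config$plateau_min_span))
  counts$n_plateaus <- nrow(plateaus)
  if (nrow(plateaus) == 0L)
    stop("stage 'plateaus' failed: no plateau found in the sweep",
         call. = FALSE)
  if (!is.null(out))
    readr::write_csv(plateaus, file.path(out, "plateaus.csv"))

  # ---- segmentation radius per plateau
  seg_radii <- switch(config$seg_rule,
    onset = plateaus$radius_start,
    midpoint = plateaus$radius_mid,
    sufficiency = {
      if (nrow(particles) < 2L) {
        plateaus$radius_start
      } else {
        r_suff <- stage("knn-radius", q, knn_radius(particles, k = config$k))
        pmin(pmax(r_suff, plateaus$radius_start), plateaus$radius_end)
      }
    })
  plateaus$radius_seg <- seg_radii

  # ---- per-plateau segmentation + thickness
  thickness <- purrr::map(seq_len(nrow(plateaus)), function(i) {
    r <- seg_radii[i]
    stage(sprintf("thickness@%gnm", r), q, {
      mask <- segment_fibers(particles, radius = r, k = config$k,
                             decimate = config$decimate)
      res <- local_thickness(mask, bin_width = config$bin_width,
                             border_exclude = config$border_exclude,
                             prune_len = config$prune_len)
      if (!is.null(out)) {
        tag <- sprintf("plateau%02d", i)
        write_mrc(vol3d(array(as.numeric(mask$data), dim(mask$data)),
                        mask$voxel_size, mask$origin),
                  file.path(out, paste0("fiber_mask_", tag, ".mrc")))
        readr::write_csv(res$radii,
                         file.path(out, paste0("radii_", tag, ".csv")))
        readr::write_csv(res$histogram,
                         file.path(out, paste0("histogram_", tag, ".csv")))
      }
      res
    })
  })
  summary_tab <- radius_report(thickness,
                               labels = sprintf("plateau_%g_nm",
                                                plateaus$radius_nm))
  if (!is.null(out)) {
    readr::write_csv(summary_tab, file.path(out, "summary.csv"))
    try(suppressMessages(ggplot2::ggsave(
      file.path(out, "histograms.png"),
      autoplot.thickness_result(thickness[[1]]),
      width = 5, height = 4, dpi = 120)), silent = TRUE)
  }

  # ---- optional FSC on phantom halves
  fsc_res <- NULL
  if (isTRUE(config$fsc) && !is.null(ph)) {
    fsc_res <- stage("fsc", q, {
      halves <- split_even_odd(ph)
      curve <- fsc_curve(halves$even, halves$odd)
      list(curve = curve,
           resolution = resolution_at(curve, config$fsc_criterion))
    })
    if (!is.null(out)) write_fsc_csv(fsc_res$curve,
                                     file.path(out, "fsc.csv"))
  }

  report <- list(config_hash = hash, seed = config$seed,
                 versions = list(
                   package = as.character(utils::packageVersion("chromothick")),
                   r = R.version.string),
                 counts = counts, sweep = sweep_tab, plateaus = plateaus,
                 thickness = thickness, summary = summary_tab,
                 fsc = fsc_res,
                 params = config_flat(config),
                 timings = proc.time()[["elapsed"]] - t_start)
  class(report) <- "run_report"
  if (!is.null(out)) {
    jsonlite::write_json(
      list(config_hash = hash, seed = config$seed,
           versions = report$versions, counts = counts,
           plateaus = plateaus, summary = summary_tab),
      file.path(out, "report.json"), auto_unbox = TRUE, digits = NA)
    write_config(config_flat(config), file.path(out, "config.cfg"))
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d particles, %d plateau(s); %.1fs\n",
              x$counts$n_particles, x$counts$n_plateaus, x$timings))
  print(x$summary)
  if (!is.null(x$fsc))
    cat(sprintf("FSC resolution: %.2f nm at %.3f (%s)\n",
                x$fsc$resolution$resolution_nm, x$fsc$resolution$criterion,
                x$fsc$resolution$flag))
  invisible(x)
}

#' Compare two pipeline runs
#'
#' Tabulates the differences in plateau radii and thickness statistics
#' between two runs with compatible configurations (same neighbor count,
#' sweep and histogram settings).
#'
#' @param report_a,report_b `run_report` objects from [run_pipeline()].
#' @return A tibble with one row per plateau position: plateau radii and
#'   modal radius / SD for both runs and their deltas.
#' @export
compare_runs <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "run_report"), inherits(report_b, "run_report"))
  keys <- c("k", "sweep_min", "sweep_max", "sweep_step", "bin_width",
            "plateau_rel_tol", "plateau_min_span")
  for (key in keys) {
    if (!identical(report_a$params[[key]], report_b$params[[key]]))
      stop(sprintf("incompatible configs: `%s` differs", key), call. = FALSE)
  }
  n <- max(nrow(report_a$summary), nrow(report_b$summary))
  pick <- function(df, col, i) if (i <= nrow(df)) df[[col]][i] else NA_real_
  purrr::map_dfr(seq_len(n), function(i) {
    tibble::tibble(
      plateau = i,
      radius_a = pick(report_a$summary, "segmentation_radius_nm", i),
      radius_b = pick(report_b$summary, "segmentation_radius_nm", i),
      delta_radius = radius_b - radius_a,
      mode_a = pick(report_a$summary, "modal_radius_nm", i),
      mode_b = pick(report_b$summary, "modal_radius_nm", i),
      delta_mode = mode_b - mode_a,
      sd_a = pick(report_a$summary, "sd_nm", i),
      sd_b = pick(report_b$summary, "sd_nm", i),
      delta_sd = sd_b - sd_a)
  })
}
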