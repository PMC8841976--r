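ps_geometry <- function(particles) {
  shape <- attr(particles, "source_shape")
  vs <- attr(particles, "voxel_size")
  orig <- attr(particles, "origin")
  if (is.null(shape) || is.null(vs))
    stop("particle set carries no grid geometry; build it with particle_set()",
         call. = FALSE)
  list(shape = as.integer(shape), voxel_size = as.numeric(vs),
       origin = if (is.null(orig)) c(0, 0, 0) else as.numeric(orig))
}

decimated_geometry <- function(geom, f) {
  list(shape = as.integer(ceiling(geom$shape / f)),
       voxel_size = geom$voxel_size * f, origin = geom$origin)
}

#' Particle-based 3D local density map
#'
#' For every voxel centre `x`, counts how many of the `k` nearest particle
#' centroids lie within the expansion radius `R` of `x` — equivalently,
#' `D(x) = min(#particles within R, k)`, so `0 <= D(x) <= k`. `k` and `R`
#' are the two parameters of the neighbor-density construction used to turn
#' discrete nanoparticles into a continuous fiber-density field
#' (defaults: `k = 40`).
#'
#' @param particles A `particle_set` (see [label_particles()],
#'   [particle_set()]).
#' @param radius Expansion radius R in nm.
#' @param k Number of closest neighbors considered per voxel (default 40).
#' @param decimate Integer grid decimation factor: the density is evaluated
#'   on a grid coarsened by this factor (default 1, the full voxel grid).
#' @param geometry Optional geometry override: a list with `shape`,
#'   `voxel_size`, `origin`.
#' @return A [vol3d()] of density values (particle counts).
#' @export
density_map <- function(particles, radius, k = 40L, decimate = 1L,
                        geometry = NULL) {
  if (nrow(particles) == 0L)
    stop("empty particle set: density map undefined", call. = FALSE)
  if (radius <= 0) stop("`radius` must be > 0", call. = FALSE)
  if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  geom <- if (is.null(geometry)) ps_geometry(particles) else geometry
  if (decimate > 1L) geom <- decimated_geometry(geom, as.integer(decimate))
  coords <- cbind(particles$z_nm, particles$y_nm, particles$x_nm)
  dens <- .density_count_cpp(coords, geom$shape, geom$voxel_size,
                             geom$origin, as.numeric(radius), as.integer(k))
  vol3d(dens, voxel_size = geom$voxel_size, origin = geom$origin)
}

count_density_objects <- function(dens, connectivity = 26L) {
  # threshold a density map and count connected components; degenerate
  # (constant) maps short-circuit: all-zero -> 0 objects, all-positive -> 1
  rng <- range(dens$data)
  if (rng[1] == rng[2]) {
    return(list(n = if (rng[1] > 0) 1L else 0L, threshold = NA_real_))
  }
  thr <- auto_threshold(dens$data)
  fg <- dens$data > thr
  if (!any(fg)) return(list(n = 0L, threshold = thr))
  lab <- .cc_label_cpp(as.logical(fg), as.integer(dim(dens$data)),
                       as.integer(connectivity))
  list(n = max(lab), threshold = thr)
}

#' Sweep the density expansion radius
#'
#' For each candidate radius, computes the density map, binarizes it with
#' the default (IsoData) threshold and counts 26-connected objects. The
#' resulting cluster-count-versus-radius curve is the basis for plateau
#' detection: stable stretches indicate a drastic change in particle
#' density, interpreted as the edge of the labeled structures.
#'
#' @inheritParams density_map
#' @param radii Strictly increasing radii in nm.
#' @return A `radius_sweep` tibble with columns `radius_nm`, `n_objects`,
#'   `threshold`; `k` and the grid geometry are kept as attributes.
#' @export
sweep_radii <- function(particles, radii, k = 40L, decimate = 1L,
                        geometry = NULL) {
  if (nrow(particles) == 0L)
    stop("empty particle set: nothing to sweep", call. = FALSE)
  radii <- as.numeric(radii)
  if (length(radii) < 1L || any(radii <= 0) ||
      (length(radii) > 1L && any(diff(radii) <= 0)))
    stop("`radii` must be strictly increasing and positive", call. = FALSE)
  rows <- purrr::map(radii, function(r) {
    dens <- density_map(particles, radius = r, k = k, decimate = decimate,
                        geometry = geometry)
    cnt <- count_density_objects(dens)
    tibble::tibble(radius_nm = r, n_objects = cnt$n, threshold = cnt$threshold)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "k") <- as.integer(k)
  attr(out, "decimate") <- as.integer(decimate)
  class(out) <- c("radius_sweep", class(out))
  out
}

#' Detect plateaus in a cluster-count curve
#'
#' A plateau is a maximal run of at least `min_span` consecutive radii
#' whose object counts all lie within `rel_tol` (relative) of the run's
#' median count. Typically two plateaus are seen on labeled-chromatin
#' data, giving two segmentation scales.
#'
#' Each plateau's representative radius `radius_nm` is, by default, the
#' first radius of the run (`"onset"`): the plateau marks the scale at
#' which the object count stops changing — the edge of the labeled
#' objects — and that scale is its beginning, not its middle. Growing the
#' density radius further only dilates the segmented objects without
#' changing their count, so segmenting at the run midpoint
#' (`representative = "midpoint"`, also returned as `radius_mid`)
#' overestimates fiber size when plateaus are long.
#'
#' @param sweep A `radius_sweep` (or any data frame with `radius_nm` and
#'   `n_objects`).
#' @param rel_tol Relative tolerance around the run median (default 0.05).
#' @param min_span Minimum run length in sweep points (default 3).
#' @param representative `"onset"` (default) or `"midpoint"`.
#' @return A tibble with one row per plateau: `plateau`, `radius_nm`
#'   (the representative), `radius_start`, `radius_mid`, `radius_end`,
#'   `n_objects` (run median), `span`. Zero rows when no plateau exists.
#' @examples
#' sw <- tibble::tibble(radius_nm = seq(10, 100, 10),
#'                      n_objects = c(100, 60, 40, 40, 40, 25, 12, 12, 12, 3))
#' detect_plateaus(sw) # runs 30-50 and 70-90 nm
#' @export
detect_plateaus <- function(sweep, rel_tol = 0.05, min_span = 3L,
                            representative = c("onset", "midpoint")) {
  representative <- match.arg(representative)
  stopifnot(all(c("radius_nm", "n_objects") %in% names(sweep)))
  if (nrow(sweep) < min_span)
    stop("sweep has fewer entries than `min_span`", call. = FALSE)
  r <- sweep$radius_nm
  cnt <- sweep$n_objects
  n <- length(cnt)
  in_tol <- function(i, j) {
    med <- stats::median(cnt[i:j])
    all(abs(cnt[i:j] - med) <= rel_tol * med)
  }
  runs <- list()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && in_tol(i, j + 1L)) j <- j + 1L
    if (j - i + 1L >= min_span) {
      runs[[length(runs) + 1L]] <-
        tibble::tibble(radius_start = r[i],
                       radius_mid = (r[i] + r[j]) / 2,
                       radius_end = r[j],
                       n_objects = stats::median(cnt[i:j]),
                       span = j - i + 1L)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out <- dplyr::bind_rows(runs)
  if (nrow(out) == 0L)
    return(tibble::tibble(plateau = integer(), radius_nm = numeric(),
                          radius_start = numeric(), radius_mid = numeric(),
                          radius_end = numeric(), n_objects = numeric(),
                          span = integer()))
  out$radius_nm <- if (representative == "onset") out$radius_start
                   else out$radius_mid
  out <- dplyr::arrange(out, .data$radius_nm)
  dplyr::select(dplyr::mutate(out, plateau = dplyr::row_number()),
                "plateau", "radius_nm", "radius_start", "radius_mid",
                "radius_end", "n_objects", "span")
}

#' Segment fiber structures at a chosen density radius
#'
#' Computes the density map at the given (usually plateau) radius and
#' binarizes it with the default IsoData threshold. The resulting objects
#' are the higher-order structures whose thickness is then measured.
#'
#' @inheritParams density_map
#' @param radius Density radius in nm, usually one returned by
#'   [detect_plateaus()].
#' @param upsample When the density grid is decimated, trilinearly upsample
#'   the map back to the full voxel grid before thresholding (default
#'   TRUE).
#' @param fill_holes Fill enclosed background cavities in the mask
#'   (default TRUE). Because the density field is sampled from discrete
#'   particles, object interiors contain spurious sampling holes that
#'   would otherwise corrupt the medial-axis distance sampling.
#' @return A `fiber_mask`: logical [vol3d()] with attributes `radius_nm`
#'   and `threshold`.
#' @export
segment_fibers <- function(particles, radius, k = 40L, decimate = 1L,
                           geometry = NULL, upsample = TRUE,
                           fill_holes = TRUE) {
  geom_full <- if (is.null(geometry)) ps_geometry(particles) else geometry
  dens <- density_map(particles, radius = radius, k = k, decimate = decimate,
                      geometry = geometry)
  if (decimate > 1L && upsample) {
    fine <- .upsample_trilinear_cpp(dens$data, dim(dens$data),
                                    dens$voxel_size, dens$origin,
                                    geom_full$shape, geom_full$voxel_size,
                                    geom_full$origin)
    dens <- vol3d(fine, voxel_size = geom_full$voxel_size,
                  origin = geom_full$origin)
  }
  rng <- range(dens$data)
  if (rng[1] == rng[2] && rng[1] == 0)
    stop("empty segmentation: density map is zero everywhere", call. = FALSE)
  if (rng[1] == rng[2]) {
    fg <- array(TRUE, dim(dens$data))
    thr <- NA_real_
  } else {
    thr <- auto_threshold(dens$data)
    fg <- dens$data > thr
  }
  if (!any(fg))
    stop("empty segmentation: no voxel above the density threshold",
         call. = FALSE)
  if (fill_holes) fg <- fill_mask_holes(array(fg, dim(dens$data)))
  mask <- vol3d(array(fg, dim(dens$data)), voxel_size = dens$voxel_size,
                origin = dens$origin)
  attr(mask, "radius_nm") <- radius
  attr(mask, "threshold") <- thr
  class(mask) <- c("fiber_mask", class(mask))
  mask
}

#' Neighborhood saturation radius of a particle set
#'
#' The median, over particles, of the distance to the k-th nearest other
#' particle. At this expansion radius a typical voxel inside a labeled
#' structure counts `k` neighbors, so the density map saturates its cap
#' and the automatic threshold (about half the cap) places the object
#' boundary at the half-density surface — the statistically best-resolved
#' segmentation scale for a given labeling density.
#'
#' @param particles A `particle_set`.
#' @param k Neighbor count (default 40, as in [density_map()]).
#' @return Radius in nm.
#' @export
knn_radius <- function(particles, k = 40L) {
  n <- nrow(particles)
  if (n < 2L) stop("need at least 2 particles", call. = FALSE)
  k <- min(k, n - 1L)
  pts <- cbind(particles$z_nm, particles$y_nm, particles$x_nm)
  # the median is estimated on a deterministic subsample of query points;
  # distances are still taken to every particle
  qidx <- if (n > 2000L) round(seq(1L, n, length.out = 2000L)) else seq_len(n)
  chunk <- max(1L, floor(2e6 / n))
  starts <- seq(1L, length(qidx), by = chunk)
  dk <- numeric(length(qidx))
  for (s in starts) {
    rows <- qidx[s:min(s + chunk - 1L, length(qidx))]
    d2 <- outer(pts[rows, 1], pts[, 1], "-")^2 +
          outer(pts[rows, 2], pts[, 2], "-")^2 +
          outer(pts[rows, 3], pts[, 3], "-")^2
    dk[s:(s + length(rows) - 1L)] <-
      apply(d2, 1, function(row) sqrt(sort(row, partial = k + 1L)[k + 1L]))
  }
  stats::median(dk)
}

fill_mask_holes <- function(fg) {
  # background components (6-connected) that do not touch the volume
  # border are enclosed cavities: make them foreground
  d <- dim(fg)
  lab <- array(.cc_label_cpp(as.logical(!fg), as.integer(d), 6L), d)
  border <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ],
                     lab[, , c(1, d[3])]))
  border <- border[border > 0L]
  fg | !(lab %in% border | lab == 0L)
}
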