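#' Automatic global threshold of an intensity sample
#'
#' Computes a global threshold from the intensity histogram. The default
#' `"isodata"` method is the iterative intermeans rule: starting from the
#' histogram midpoint, the threshold is moved to the mean of the
#' below-threshold and above-threshold class means until it stabilizes
#' (the rule behind the "default" automatic threshold of common image
#' analysis tools). `"otsu"` maximizes between-class variance instead.
#'
#' @param x Numeric vector or array of intensities.
#' @param method `"isodata"` (default) or `"otsu"`.
#' @param n_bins Number of histogram bins (default 256).
#' @return The threshold value, on the intensity scale. Foreground is
#'   defined as strictly greater than the threshold.
#' @export
auto_threshold <- function(x, method = c("isodata", "otsu"), n_bins = 256L) {
  method <- match.arg(method)
  x <- as.numeric(x)
  rng <- range(x)
  if (rng[1] == rng[2])
    stop("degenerate input: constant intensity, no threshold separates anything",
         call. = FALSE)
  bw <- diff(rng) / n_bins
  # bin index 1..n_bins; top value goes in the last bin
  idx <- pmin(floor((x - rng[1]) / bw) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) * bw
  if (method == "isodata") {
    # iterative intermeans on bin indices: classes are bins [1..g] and
    # [g+1..n]; g is moved to the rounded midpoint of the two class means
    # until it is a fixed point (the map is monotone, so iterating from
    # below converges to the least fixed point without cycling)
    bins <- seq_len(n_bins)
    csum <- cumsum(counts)
    cidx <- cumsum(counts * bins)
    total_n <- csum[n_bins]
    total_s <- cidx[n_bins]
    g <- which(counts > 0)[1]
    repeat {
      n_lo <- csum[g]
      n_hi <- total_n - n_lo
      if (n_hi == 0L) { g <- g - 1L; next }
      m_lo <- cidx[g] / n_lo
      m_hi <- (total_s - cidx[g]) / n_hi
      g_new <- as.integer(round((m_lo + m_hi) / 2))
      g_new <- max(1L, min(n_bins - 1L, g_new))
      if (g_new == g) break
      g <- g_new
    }
    # threshold at the upper edge of bin g: split is (<= t, > t)
    rng[1] + g * bw
  } else {
    w <- counts / sum(counts)
    mu <- cumsum(w * mids)
    omega <- cumsum(w)
    mu_t <- mu[n_bins]
    sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
    sigma_b[!is.finite(sigma_b)] <- -Inf
    g <- which.max(sigma_b)
    rng[1] + g * bw
  }
}

#' Binarize a volume with an automatic global threshold
#'
#' Converts a grayscale tomogram into a binary image; foreground voxels are
#' those strictly above the computed threshold.
#'
#' @param vol A [vol3d()].
#' @param method Threshold method, see [auto_threshold()].
#' @param n_bins Histogram bins for threshold estimation.
#' @return A list with `mask` (a logical `vol3d` of identical geometry) and
#'   `threshold` (the intensity value used).
#' @examples
#' v <- vol3d(array(c(rep(0, 500), rep(100, 12)), c(8, 8, 8)), 4)
#' b <- binarize(v)
#' sum(b$mask$data) # 12
#' @export
binarize <- function(vol, method = c("isodata", "otsu"), n_bins = 256L) {
  stopifnot(is_vol3d(vol))
  thr <- auto_threshold(vol$data, method = method, n_bins = n_bins)
  mask <- vol3d(array(vol$data > thr, dim(vol$data)),
                voxel_size = vol$voxel_size, origin = vol$origin)
  list(mask = mask, threshold = thr)
}

#' Label 3D particles in a binary volume
#'
#' Finds connected components of the foreground under 6-, 18- or
#' 26-connectivity, discards components smaller than `min_voxels`, and
#' returns one row per particle with its centroid in physical (nm)
#' coordinates — the mean of the member voxel centres.
#'
#' @param mask Logical `vol3d` (or a list as returned by [binarize()]).
#' @param connectivity 6, 18 or 26 (default 26).
#' @param min_voxels Minimum component size in voxels (default 2).
#' @return A `particle_set`: a tibble with columns `id`, `z_nm`, `y_nm`,
#'   `x_nm`, `voxels`, carrying the source geometry and the discarded voxel
#'   count as attributes.
#' @export
label_particles <- function(mask, connectivity = 26L, min_voxels = 2L) {
  if (is.list(mask) && !is_vol3d(mask) && !is.null(mask$mask)) mask <- mask$mask
  stopifnot(is_vol3d(mask))
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("`connectivity` must be 6, 18 or 26", call. = FALSE)
  d <- dim(mask$data)
  lab <- .cc_label_cpp(as.logical(mask$data), as.integer(d),
                       as.integer(connectivity))
  fg <- which(lab > 0L)
  if (length(fg) == 0L) {
    return(new_particle_set(tibble::tibble(id = integer(), z_nm = numeric(),
                                           y_nm = numeric(), x_nm = numeric(),
                                           voxels = integer()),
                            mask, discarded_voxels = 0L))
  }
  labs <- lab[fg]
  # voxel indices (1-based) along each axis
  iz <- ((fg - 1L) %% d[1]) + 1L
  iy <- (((fg - 1L) %/% d[1]) %% d[2]) + 1L
  ix <- ((fg - 1L) %/% (d[1] * d[2])) + 1L
  vs <- mask$voxel_size; orig <- mask$origin
  df <- tibble::tibble(
    lab = labs,
    z = (iz - 0.5) * vs[1] + orig[1],
    y = (iy - 0.5) * vs[2] + orig[2],
    x = (ix - 0.5) * vs[3] + orig[3])
  agg <- dplyr::summarise(dplyr::group_by(df, .data$lab),
                          z_nm = mean(.data$z), y_nm = mean(.data$y),
                          x_nm = mean(.data$x), voxels = dplyr::n(),
                          .groups = "drop")
  keep <- agg$voxels >= min_voxels
  discarded <- sum(agg$voxels[!keep])
  agg <- agg[keep, , drop = FALSE]
  out <- tibble::tibble(id = seq_len(nrow(agg)),
                        z_nm = agg$z_nm, y_nm = agg$y_nm, x_nm = agg$x_nm,
                        voxels = as.integer(agg$voxels))
  new_particle_set(out, mask, discarded_voxels = as.integer(discarded))
}

new_particle_set <- function(df, geom, discarded_voxels = 0L) {
  attr(df, "source_shape") <- dim(geom$data)
  attr(df, "voxel_size") <- geom$voxel_size
  attr(df, "origin") <- geom$origin
  attr(df, "discarded_voxels") <- discarded_voxels
  class(df) <- c("particle_set", class(df))
  df
}

#' Detect particles in a grayscale volume
#'
#' Convenience wrapper: [binarize()] then [label_particles()].
#'
#' @inheritParams binarize
#' @inheritParams label_particles
#' @return A `particle_set` tibble; the threshold used is stored in the
#'   `threshold` attribute.
#' @export
detect_particles <- function(vol, method = c("isodata", "otsu"),
                             connectivity = 26L, min_voxels = 2L) {
  b <- binarize(vol, method = method)
  ps <- label_particles(b$mask, connectivity = connectivity,
                        min_voxels = min_voxels)
  attr(ps, "threshold") <- b$threshold
  ps
}

#' Build a particle set from bare coordinates
#'
#' Used when particle centroids come from a CSV instead of a volume.
#'
#' @param coords Data frame with columns `z_nm`, `y_nm`, `x_nm` (and
#'   optionally `id`, `voxels`).
#' @param voxel_size Grid voxel size in nm for downstream density maps.
#' @param shape Grid shape `(z,y,x)` in voxels; defaults to the smallest
#'   grid covering the coordinates.
#' @param origin Grid origin in nm.
#' @return A `particle_set` tibble.
#' @export
particle_set <- function(coords, voxel_size, shape = NULL,
                         origin = c(0, 0, 0)) {
  stopifnot(all(c("z_nm", "y_nm", "x_nm") %in% names(coords)))
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  origin <- rep_len(as.numeric(origin), 3L)
  if (is.null(shape)) {
    shape <- ceiling((c(max(coords$z_nm), max(coords$y_nm), max(coords$x_nm)) -
                        origin) / voxel_size)
    shape <- pmax(shape, 1)
  }
  df <- tibble::tibble(
    id = if ("id" %in% names(coords)) coords$id else seq_len(nrow(coords)),
    z_nm = coords$z_nm, y_nm = coords$y_nm, x_nm = coords$x_nm,
    voxels = if ("voxels" %in% names(coords)) as.integer(coords$voxels)
             else rep(1L, nrow(coords)))
  geom <- list(data = array(0, shape), voxel_size = voxel_size,
               origin = origin)
  new_particle_set(df, geom)
}

#' Write / read particle sets as CSV
#'
#' Columns: `id, z_nm, y_nm, x_nm, voxels`.
#'
#' @param ps A `particle_set`.
#' @param path CSV path.
#' @return `path` (write) or a `particle_set` (read).
#' @export
write_particles_csv <- function(ps, path) {
  readr::write_csv(tibble::as_tibble(ps), path)
  invisible(path)
}

#' @rdname write_particles_csv
#' @param voxel_size,shape,origin Grid geometry, see [particle_set()].
#' @export
read_particles_csv <- function(path, voxel_size, shape = NULL,
                               origin = c(0, 0, 0)) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  particle_set(df, voxel_size = voxel_size, shape = shape, origin = origin)
}
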