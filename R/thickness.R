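#' Euclidean distance map of a binary volume
#'
#' For every foreground voxel, the exact Euclidean distance (nm, honoring
#' anisotropic voxel size) to the centre of the nearest background voxel;
#' background voxels get 0. The volume faces are treated as background, so
#' voxels beyond the slab truncate distances — as physical sectioning does.
#'
#' @param mask Logical [vol3d()].
#' @return A [vol3d()] of distances in nm.
#' @export
distance_map <- function(mask) {
  stopifnot(is_vol3d(mask))
  if (!any(mask$data))
    stop("empty mask: distance map undefined", call. = FALSE)
  d <- dim(mask$data)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask$data
  dsq <- .edt_sq_cpp(as.logical(pad), as.integer(d + 2L), mask$voxel_size)
  dist <- sqrt(array(dsq, d + 2L)[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)])
  vol3d(array(dist, d), voxel_size = mask$voxel_size, origin = mask$origin)
}

iso_resample_mask <- function(mask) {
  # nearest-neighbour resampling onto an isotropic grid at the finest
  # voxel size; returns the resampled array plus the mapping back
  vs <- mask$voxel_size
  iso <- min(vs)
  d <- dim(mask$data)
  nd <- pmax(1L, as.integer(round(d * vs / iso)))
  idx <- lapply(1:3, function(a) {
    centers <- (seq_len(nd[a]) - 0.5) * iso
    pmin(pmax(ceiling(centers / vs[a]), 1L), d[a])
  })
  arr <- mask$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  list(data = array(arr, nd), iso = iso, map = idx)
}

#' Medial-axis skeleton of a binary volume
#'
#' One-voxel-thick 26-connected curve skeleton produced by 3D topological
#' thinning: border voxels that are simple points (their removal preserves
#' both object 26-connectivity and background 6-connectivity in the local
#' neighbourhood) are peeled in six directional subiterations until
#' stable; curve endpoints are preserved. Anisotropic volumes are
#' resampled to an isotropic grid before thinning and the skeleton is
#' mapped back. Spurious side branches shorter than `prune_len` voxels
#' are pruned.
#'
#' @param mask Logical [vol3d()].
#' @param prune_len Remove terminal branches shorter than this many voxels
#'   (default 3); 0 disables pruning.
#' @return A logical [vol3d()] in the geometry of `mask`; skeleton voxels
#'   are a subset of the mask foreground.
#' @export
skeletonize <- function(mask, prune_len = 3L) {
  stopifnot(is_vol3d(mask))
  if (!any(mask$data))
    stop("empty mask: nothing to skeletonize", call. = FALSE)
  vs <- mask$voxel_size
  d <- dim(mask$data)
  if (max(vs) / min(vs) > 1.001) {
    rs <- iso_resample_mask(mask)
    thin <- .thin3d_cpp(as.logical(rs$data), as.integer(dim(rs$data)))
    thin <- array(thin, dim(rs$data))
    # map isotropic skeleton voxels back to original voxel indices
    w <- which(thin)
    nd <- dim(rs$data)
    iz <- rs$map[[1]][((w - 1L) %% nd[1]) + 1L]
    iy <- rs$map[[2]][(((w - 1L) %/% nd[1]) %% nd[2]) + 1L]
    ix <- rs$map[[3]][((w - 1L) %/% (nd[1] * nd[2])) + 1L]
    sk <- array(FALSE, d)
    sk[cbind(iz, iy, ix)] <- TRUE
    sk <- sk & mask$data
  } else {
    sk <- array(.thin3d_cpp(as.logical(mask$data), as.integer(d)), d)
  }
  if (prune_len > 0L) sk <- prune_skeleton(sk, prune_len)
  out <- vol3d(sk, voxel_size = vs, origin = mask$origin)
  class(out) <- c("skeleton3d", class(out))
  out
}

prune_skeleton <- function(sk, prune_len) {
  d <- dim(sk)
  w <- which(sk)
  if (length(w) == 0L) return(sk)
  iz <- ((w - 1L) %% d[1]) + 1L
  iy <- (((w - 1L) %/% d[1]) %% d[2]) + 1L
  ix <- ((w - 1L) %/% (d[1] * d[2])) + 1L
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0L, , drop = FALSE]
  nsk <- length(w)
  # vectorized 26-neighbour adjacency within the skeleton: for each of the
  # 26 offsets, which skeleton voxel (if any) sits there
  adj <- matrix(NA_integer_, nsk, 26L)
  for (o in seq_len(26L)) {
    zz <- iz + offs[o, 1]; yy <- iy + offs[o, 2]; xx <- ix + offs[o, 3]
    ok <- zz >= 1L & zz <= d[1] & yy >= 1L & yy <= d[2] &
          xx >= 1L & xx <= d[3]
    keys <- rep(NA_real_, nsk)
    keys[ok] <- (xx[ok] - 1) * (as.numeric(d[1]) * d[2]) +
                (yy[ok] - 1) * d[1] + zz[ok]
    adj[, o] <- match(keys, as.numeric(w))
  }
  alive <- rep(TRUE, nsk)
  degree <- function(i) sum(alive[adj[i, ]], na.rm = TRUE)
  deg0 <- rowSums(matrix(alive[adj], nsk, 26L), na.rm = TRUE)
  endpoints <- which(deg0 <= 1L)
  for (e in endpoints) {
    if (!alive[e]) next
    path <- integer(0)
    cur <- e
    prev <- 0L
    repeat {
      path <- c(path, cur)
      if (length(path) >= prune_len) break  # long enough: keep
      nb <- adj[cur, ]
      nb <- nb[!is.na(nb)]
      nb <- nb[alive[nb] & nb != prev]
      if (length(nb) != 1L) break           # isolated or odd local shape
      nxt <- nb
      if (degree(nxt) > 2L) {
        # the branch meets a junction before reaching prune_len: drop it
        alive[path] <- FALSE
        break
      }
      prev <- cur
      cur <- nxt
    }
  }
  if (all(alive)) return(sk)
  out <- array(FALSE, d)
  out[w[alive]] <- TRUE
  out
}

#' Local fiber thickness along the medial axis
#'
#' Samples the Euclidean distance map at the skeleton voxels of a fiber
#' mask: each sample is the local fiber radius (distance from the central
#' axis to the nearest object edge). Radii are histogrammed; the modal
#' radius is the centre of the most populated bin refined by a 3-point
#' quadratic interpolation over the bins around the mode. SE is
#' `sd / sqrt(n)` over the sampled skeleton voxels.
#'
#' Skeleton voxels closer to the slab's z faces than their own measured
#' radius have face-truncated distances (an artifact of physical
#' sectioning) and are excluded from the histogram when
#' `border_exclude = TRUE`.
#'
#' @param mask Logical [vol3d()] fiber mask (see [segment_fibers()]).
#' @param bin_width Histogram bin width in nm (default 5).
#' @param border_exclude Drop skeleton voxels whose distance may be
#'   truncated by the z faces (default TRUE).
#' @param prune_len Skeleton branch pruning, see [skeletonize()]; the
#'   string `"adaptive"` prunes branches shorter than 80% of the mask's
#'   maximum inscribed radius (in voxels, at least 5) — thick objects
#'   grow medial-axis side branches toward every surface bump, up to one
#'   object radius long, and these would otherwise dominate the radius
#'   histogram.
#' @return A `thickness_result`: list with `radii` (tibble `z`, `y`, `x`,
#'   `radius_nm`, `excluded`), `histogram` (tibble `mid_nm`, `count`),
#'   `modal_radius_nm`, `sd_nm`, `se_nm`, `n`, `bin_width`.
#' @export
local_thickness <- function(mask, bin_width = 5, border_exclude = TRUE,
                            prune_len = 3L) {
  stopifnot(is_vol3d(mask))
  dm <- distance_map(mask)
  if (identical(prune_len, "adaptive"))
    prune_len <- max(5L, as.integer(ceiling(
      0.8 * max(dm$data) / min(mask$voxel_size))))
  sk <- skeletonize(mask, prune_len = prune_len)
  w <- which(sk$data)
  if (length(w) == 0L)
    stop("skeleton is empty after thinning", call. = FALSE)
  d <- dim(mask$data)
  iz <- ((w - 1L) %% d[1]) + 1L
  iy <- (((w - 1L) %/% d[1]) %% d[2]) + 1L
  ix <- ((w - 1L) %/% (d[1] * d[2])) + 1L
  radii <- dm$data[w]
  vsz <- mask$voxel_size[1]
  zface <- pmin(iz, d[1] + 1L - iz) * vsz  # distance to nearest outside centre
  excluded <- if (border_exclude) zface <= radii + 0.5 * vsz
              else rep(FALSE, length(w))
  tab <- tibble::tibble(z = iz, y = iy, x = ix, radius_nm = radii,
                        excluded = excluded)
  use <- radii[!excluded]
  if (length(use) == 0L)
    stop("all skeleton voxels were excluded by the border rule", call. = FALSE)
  hist_mode <- radius_histogram(use, bin_width)
  res <- list(radii = tab, histogram = hist_mode$histogram,
              modal_radius_nm = hist_mode$mode,
              sd_nm = if (length(use) > 1L) stats::sd(use) else 0,
              se_nm = if (length(use) > 1L)
                        stats::sd(use) / sqrt(length(use)) else 0,
              n = length(use), bin_width = bin_width,
              segmentation_radius_nm = attr(mask, "radius_nm"))
  class(res) <- "thickness_result"
  res
}

radius_histogram <- function(radii, bin_width) {
  if (length(unique(radii)) == 1L) {
    # degenerate: a single observed radius is its own mode
    mid <- radii[1]
    return(list(histogram = tibble::tibble(mid_nm = mid,
                                           count = length(radii)),
                mode = mid))
  }
  breaks <- seq(0, max(radii) + bin_width, by = bin_width)
  cuts <- pmin(findInterval(radii, breaks, rightmost.closed = FALSE),
               length(breaks) - 1L)
  counts <- tabulate(cuts, nbins = length(breaks) - 1L)
  mids <- breaks[-length(breaks)] + bin_width / 2
  m <- which.max(counts)
  mode <- mids[m]
  if (m > 1L && m < length(counts)) {
    l <- counts[m - 1L]; c0 <- counts[m]; r <- counts[m + 1L]
    den <- l - 2 * c0 + r
    if (den < 0) mode <- mids[m] + 0.5 * (l - r) / den * bin_width
  }
  list(histogram = tibble::tibble(mid_nm = mids, count = counts),
       mode = mode)
}

#' @export
print.thickness_result <- function(x, ...) {
  cat(sprintf(paste0("<thickness_result> modal radius %.2f nm ",
                     "(SD %.2f, SE %.3f, n = %d skeleton voxels)\n"),
              x$modal_radius_nm, x$sd_nm, x$se_nm, x$n))
  if (!is.null(x$segmentation_radius_nm))
    cat(sprintf("  segmentation (density) radius: %g nm\n",
                x$segmentation_radius_nm))
  invisible(x)
}

#' Summary table of fiber radii per segmentation scale
#'
#' Collects one or more thickness results into a report table, one row per
#' segmentation (plateau) radius, ordered by that radius. Fiber diameter
#' is reported as twice the modal radius.
#'
#' @param results A `thickness_result`, a list of them, or a data frame
#'   that already has a `modal_radius_nm` column.
#' @param labels Optional labels, one per result.
#' @return A tibble with columns `label`, `segmentation_radius_nm`,
#'   `modal_radius_nm`, `sd_nm`, `se_nm`, `n`, `diameter_nm`.
#' @examples
#' radius_report(data.frame(modal_radius_nm = c(74.5, 90.02)))
#' @export
radius_report <- function(results, labels = NULL) {
  if (inherits(results, "thickness_result")) results <- list(results)
  if (is.data.frame(results)) {
    df <- tibble::as_tibble(results)
    if (!"modal_radius_nm" %in% names(df))
      stop("data-frame input needs a `modal_radius_nm` column", call. = FALSE)
    for (col in c("sd_nm", "se_nm"))
      if (!col %in% names(df)) df[[col]] <- NA_real_
    if (!"n" %in% names(df)) df$n <- NA_integer_
    if (!"segmentation_radius_nm" %in% names(df))
      df$segmentation_radius_nm <- NA_real_
  } else {
    if (length(results) == 0L)
      stop("need at least one thickness result", call. = FALSE)
    df <- dplyr::bind_rows(purrr::map(results, function(r) {
      tibble::tibble(
        segmentation_radius_nm =
          if (is.null(r$segmentation_radius_nm)) NA_real_
          else r$segmentation_radius_nm,
        modal_radius_nm = r$modal_radius_nm, sd_nm = r$sd_nm,
        se_nm = r$se_nm, n = r$n)
    }))
  }
  df$label <- if (is.null(labels)) paste0("scale_", seq_len(nrow(df)))
              else as.character(labels)
  df$diameter_nm <- 2 * df$modal_radius_nm
  ord <- order(ifelse(is.na(df$segmentation_radius_nm),
                      df$modal_radius_nm, df$segmentation_radius_nm))
  out <- df[ord, c("label", "segmentation_radius_nm", "modal_radius_nm",
                   "sd_nm", "se_nm", "n", "diameter_nm")]
  tibble::as_tibble(out)
}
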