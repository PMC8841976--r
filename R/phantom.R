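#' Specification of a synthetic labeled-fiber phantom
#'
#' Describes a synthetic volume that emulates nanoparticle-labeled
#' higher-order chromatin fibers in a plastic section: tube-like fibers
#' (persistent random-walk centerlines of set radius) decorated with
#' point particles at a Poisson label density, plus non-specific
#' background particles, rendered as high-contrast spherical blobs the
#' size of silver-enhanced gold particles (10-20 nm). Every field has a
#' known ground truth so downstream stages can be checked by parameter
#' recovery.
#'
#' @param volume_shape Voxels per axis `(z, y, x)`. The default slab,
#'   72 x 192 x 192 voxels at 4 nm, is 288 nm thick — a typical plastic
#'   section (250-350 nm).
#' @param voxel_size nm per axis (scalar or `(z,y,x)`).
#' @param n_fibers Number of fibers.
#' @param fiber_radius Fiber radius in nm; scalar or one value per fiber.
#' @param fiber_length Target centerline length in nm (walks are clipped
#'   at the volume faces, as sectioning clips real fibers).
#' @param step_length Centerline segment length in nm.
#' @param persistence Directional correlation of successive steps in
#'   `[0, 1]`: the expected cosine between successive step directions.
#'   1 gives straight fibers, 0 an uncorrelated random walk.
#' @param min_separation Minimum axis-to-axis distance between fiber
#'   centerlines in nm (whole paths are rejection-sampled), emulating
#'   distinct fibers in a section; 0 disables.
#' @param label_density Particles per nm^3 of fiber (tube) volume. The
#'   default 2e-4 (mean particle spacing ~17 nm) is the high-density
#'   labeling regime: neighbor counts saturate the `k = 40` cap inside
#'   fibers at expansion radii below the fiber radius.
#' @param noise_density Background particles per nm^3 of volume.
#' @param particle_radius Rendered particle blob radius in nm (default 6,
#'   i.e. 12 nm diameter silver-enhanced particles).
#' @param particle_intensity Blob intensity in arbitrary units.
#' @param blob `"sphere"` (hard-edged, default — matches high-contrast
#'   metal particles) or `"gaussian"`.
#' @param seed Master seed; expanded deterministically into independent
#'   per-stage substreams, so e.g. adding fibers does not perturb the
#'   background noise.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(volume_shape = c(72L, 192L, 192L), voxel_size = 4,
                         n_fibers = 4L, fiber_radius = 75,
                         fiber_length = 1000, step_length = 40,
                         persistence = 0.97, min_separation = 300,
                         label_density = 2e-4, noise_density = 2e-7,
                         particle_radius = 6, particle_intensity = 100,
                         blob = c("sphere", "gaussian"), seed = 1L) {
  blob <- match.arg(blob)
  volume_shape <- as.integer(rep_len(volume_shape, 3L))
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(volume_shape < 1L))
    stop("`volume_shape` must be strictly positive on all axes", call. = FALSE)
  if (any(voxel_size <= 0)) stop("`voxel_size` must be > 0", call. = FALSE)
  if (n_fibers < 0L) stop("`n_fibers` must be >= 0", call. = FALSE)
  fiber_radius <- as.numeric(fiber_radius)
  if (any(fiber_radius <= 0)) stop("`fiber_radius` must be > 0", call. = FALSE)
  if (n_fibers > 0L) fiber_radius <- rep_len(fiber_radius, n_fibers)
  if (step_length <= 0)
    stop("invalid spec: `step_length` must be > 0", call. = FALSE)
  if (fiber_length <= 0) stop("`fiber_length` must be > 0", call. = FALSE)
  if (persistence < 0 || persistence > 1)
    stop("`persistence` must lie in [0, 1]", call. = FALSE)
  if (label_density < 0 || noise_density < 0)
    stop("densities must be >= 0", call. = FALSE)
  if (particle_radius <= 0) stop("`particle_radius` must be > 0", call. = FALSE)
  structure(list(volume_shape = volume_shape, voxel_size = voxel_size,
                 n_fibers = as.integer(n_fibers),
                 fiber_radius = fiber_radius, fiber_length = fiber_length,
                 step_length = step_length, persistence = persistence,
                 min_separation = min_separation,
                 label_density = label_density,
                 noise_density = noise_density,
                 particle_radius = particle_radius,
                 particle_intensity = particle_intensity,
                 blob = blob, seed = as.integer(seed)),
            class = "phantom_spec")
}

# deterministic substream seed, kept below 2^31
derive_seed <- function(master, stage) {
  as.integer((as.numeric(master) %% 65011) * 33013 + stage * 7919) %% 2147483629L
}

box_extent <- function(spec) spec$volume_shape * spec$voxel_size

# unit vector uniform on the sphere
runif_sphere <- function() {
  u <- stats::runif(1, -1, 1)
  phi <- stats::runif(1, 0, 2 * pi)
  s <- sqrt(1 - u^2)
  c(u, s * cos(phi), s * sin(phi))
}

# new direction with E[cos(angle to `dir`)] = p: cos ~ U(2p - 1, 1),
# azimuth uniform about `dir`
persistent_step <- function(dir, p) {
  ct <- stats::runif(1, 2 * p - 1, 1)
  st <- sqrt(max(0, 1 - ct^2))
  phi <- stats::runif(1, 0, 2 * pi)
  # orthonormal basis perpendicular to dir
  a <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * dir) * dir
  u <- u / sqrt(sum(u^2))
  v <- c(dir[2] * u[3] - dir[3] * u[2],
         dir[3] * u[1] - dir[1] * u[3],
         dir[1] * u[2] - dir[2] * u[1])
  ct * dir + st * (cos(phi) * u + sin(phi) * v)
}

#' Generate fiber centerlines
#'
#' Fixed-step persistent random walks: points spaced `step_length` apart,
#' successive directions with expected cosine `persistence`, clipped at
#' the volume faces. Deterministic for a fixed seed.
#'
#' @param spec A [phantom_spec()].
#' @return List of polylines, each an `n x 3` matrix of `(z, y, x)` points
#'   in nm.
#' @export
generate_centerlines <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$n_fibers == 0L) return(list())
  ext <- box_extent(spec)
  n_steps <- max(1L, ceiling(spec$fiber_length / spec$step_length))
  out <- vector("list", spec$n_fibers)
  prev_pts <- matrix(NA_real_, 0, 3)
  walk_one <- function() {
    # grow in both directions from an inset seed point so that fibers are
    # not cut short the moment the forward walk meets a face; clipping at
    # the slab faces mirrors physical sectioning
    p0 <- (0.1 + 0.8 * stats::runif(3)) * ext
    d0 <- runif_sphere()
    grow <- function(start, dir, budget) {
      pts <- NULL
      cur <- start
      for (s in seq_len(budget)) {
        nxt <- cur + spec$step_length * dir
        if (any(nxt < 0) || any(nxt > ext)) break
        pts <- rbind(pts, nxt)
        cur <- nxt
        dir <- persistent_step(dir, spec$persistence)
      }
      pts
    }
    fwd <- grow(p0, d0, n_steps)
    used <- if (is.null(fwd)) 0L else nrow(fwd)
    bwd <- if (used < n_steps) grow(p0, -d0, n_steps - used) else NULL
    pts <- rbind(if (!is.null(bwd)) bwd[rev(seq_len(nrow(bwd))), , drop = FALSE],
                 matrix(p0, 1, 3), fwd)
    unname(pts)
  }
  for (f in seq_len(spec$n_fibers)) {
    # rejection-sample whole paths so distinct fibers stay min_separation
    # apart (axis to axis), as separate chromonema segments in a section
    # do; among acceptable paths prefer ones close to the target length
    best <- NULL
    best_score <- c(-Inf, -Inf)
    for (try in 1:40) {
      set.seed(derive_seed(spec$seed, 100L + f + 1000L * try))
      pts <- walk_one()
      len <- (nrow(pts) - 1L) * spec$step_length
      if (nrow(prev_pts) == 0L || spec$min_separation <= 0) {
        dmin <- Inf
      } else {
        dmin <- min(apply(pts, 1, function(p)
          min(sqrt(colSums((t(prev_pts) - p)^2)))))
      }
      score <- c(min(dmin, spec$min_separation), len)
      if (score[1] > best_score[1] ||
          (score[1] == best_score[1] && score[2] > best_score[2])) {
        best_score <- score
        best <- pts
      }
      if (dmin >= spec$min_separation && len >= 0.7 * spec$fiber_length)
        break
    }
    out[[f]] <- best
    prev_pts <- rbind(prev_pts, best)
  }
  out
}

centerline_segments <- function(centerlines, radii = NULL) {
  segs <- list()
  seg_radius <- numeric(0)
  seg_fiber <- integer(0)
  for (f in seq_along(centerlines)) {
    pts <- centerlines[[f]]
    if (nrow(pts) < 2L) {
      # degenerate: a single point becomes a zero-length segment
      segs[[length(segs) + 1L]] <- cbind(pts, pts)
      seg_radius <- c(seg_radius, if (is.null(radii)) NA else radii[f])
      seg_fiber <- c(seg_fiber, f)
      next
    }
    a <- pts[-nrow(pts), , drop = FALSE]
    b <- pts[-1, , drop = FALSE]
    segs[[length(segs) + 1L]] <- cbind(a, b)
    seg_radius <- c(seg_radius,
                    rep(if (is.null(radii)) NA else radii[f], nrow(a)))
    seg_fiber <- c(seg_fiber, rep(f, nrow(a)))
  }
  list(segs = do.call(rbind, segs), radius = seg_radius, fiber = seg_fiber)
}

blob_kernel <- function(spec) {
  vs <- spec$voxel_size
  r <- spec$particle_radius
  nmax <- ceiling(r * (if (spec$blob == "gaussian") 2 else 1) / vs)
  offs <- as.matrix(expand.grid(dz = -nmax[1]:nmax[1], dy = -nmax[2]:nmax[2],
                                dx = -nmax[3]:nmax[3]))
  dist <- sqrt((offs[, 1] * vs[1])^2 + (offs[, 2] * vs[2])^2 +
               (offs[, 3] * vs[3])^2)
  if (spec$blob == "sphere") {
    keep <- dist <= r
    list(offsets = offs[keep, , drop = FALSE],
         weights = rep(spec$particle_intensity, sum(keep)))
  } else {
    sigma <- r / 2
    keep <- dist <= 2 * r
    list(offsets = offs[keep, , drop = FALSE],
         weights = spec$particle_intensity * exp(-dist[keep]^2 / (2 * sigma^2)))
  }
}

render_particles <- function(coords, spec) {
  d <- spec$volume_shape
  vol <- array(0, d)
  if (nrow(coords) > 0L) {
    kern <- blob_kernel(spec)
    centers <- cbind(as.integer(round(coords[, 1] / spec$voxel_size[1] - 0.5)),
                     as.integer(round(coords[, 2] / spec$voxel_size[2] - 0.5)),
                     as.integer(round(coords[, 3] / spec$voxel_size[3] - 0.5)))
    vol <- array(.stamp_add_cpp(vol, as.integer(d), centers,
                                kern$offsets, kern$weights), d)
  }
  vol3d(vol, voxel_size = spec$voxel_size)
}

#' Decorate centerlines with particles and render the phantom volume
#'
#' Particle counts inside each fiber tube follow a Poisson law with mean
#' `label_density x tube volume`; background particles follow
#' `noise_density x volume`. Each particle is rendered as a spherical blob
#' at the nearest voxel on a zero background. Fixed seed gives
#' bit-identical output.
#'
#' @param spec A [phantom_spec()].
#' @param centerlines Polylines from [generate_centerlines()]; defaults to
#'   generating them from `spec`.
#' @return A `phantom`: list with `volume` ([vol3d()]), `particles`
#'   (a `particle_set` tibble with a `fiber` column, 0 for background
#'   noise), `truth_mask` (logical [vol3d()] of the fiber tubes),
#'   `centerlines`, and `spec`.
#' @export
decorate_and_render <- function(spec, centerlines = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(centerlines)) centerlines <- generate_centerlines(spec)
  ext <- box_extent(spec)
  coords <- matrix(NA_real_, 0, 3)
  fiber_id <- integer(0)
  for (f in seq_along(centerlines)) {
    set.seed(derive_seed(spec$seed, 10000L + f))
    pts <- centerlines[[f]]
    if (nrow(pts) < 2L) next
    a <- pts[-nrow(pts), , drop = FALSE]
    b <- pts[-1, , drop = FALSE]
    seg_len <- sqrt(rowSums((b - a)^2))
    r <- spec$fiber_radius[f]
    tube_vol <- sum(seg_len) * pi * r^2
    n <- stats::rpois(1, spec$label_density * tube_vol)
    if (n == 0L) next
    seg <- sample.int(length(seg_len), n, replace = TRUE, prob = seg_len)
    t <- stats::runif(n)
    base <- a[seg, , drop = FALSE] + t * (b - a)[seg, , drop = FALSE]
    dirs <- (b - a)[seg, , drop = FALSE] / seg_len[seg]
    # uniform over the disc perpendicular to the local direction
    rr <- r * sqrt(stats::runif(n))
    ang <- stats::runif(n, 0, 2 * pi)
    ref <- ifelse(abs(dirs[, 1]) < 0.9, 1, 0)
    aa <- cbind(ref, 1 - ref, 0)
    u <- aa - rowSums(aa * dirs) * dirs
    u <- u / sqrt(rowSums(u^2))
    v <- cbind(dirs[, 2] * u[, 3] - dirs[, 3] * u[, 2],
               dirs[, 3] * u[, 1] - dirs[, 1] * u[, 3],
               dirs[, 1] * u[, 2] - dirs[, 2] * u[, 1])
    p <- base + rr * (cos(ang) * u + sin(ang) * v)
    inside <- p[, 1] >= 0 & p[, 1] <= ext[1] & p[, 2] >= 0 &
              p[, 2] <= ext[2] & p[, 3] >= 0 & p[, 3] <= ext[3]
    coords <- rbind(coords, p[inside, , drop = FALSE])
    fiber_id <- c(fiber_id, rep(f, sum(inside)))
  }
  set.seed(derive_seed(spec$seed, 20000L))
  n_noise <- stats::rpois(1, spec$noise_density * prod(ext))
  if (n_noise > 0L) {
    pn <- cbind(stats::runif(n_noise, 0, ext[1]),
                stats::runif(n_noise, 0, ext[2]),
                stats::runif(n_noise, 0, ext[3]))
    coords <- rbind(coords, pn)
    fiber_id <- c(fiber_id, rep(0L, n_noise))
  }
  vol <- render_particles(coords, spec)
  segs <- centerline_segments(centerlines, spec$fiber_radius)
  truth <- if (is.null(segs$segs)) {
    array(FALSE, spec$volume_shape)
  } else {
    array(.capsule_mask_cpp(segs$segs, segs$radius,
                            as.integer(spec$volume_shape),
                            spec$voxel_size, c(0, 0, 0)),
          spec$volume_shape)
  }
  particles <- tibble::tibble(
    id = seq_len(nrow(coords)),
    z_nm = coords[, 1], y_nm = coords[, 2], x_nm = coords[, 3],
    voxels = rep(1L, nrow(coords)), fiber = fiber_id)
  particles <- new_particle_set(particles, vol)
  out <- list(volume = vol,
              particles = particles,
              truth_mask = vol3d(truth, voxel_size = spec$voxel_size),
              centerlines = centerlines,
              spec = spec)
  class(out) <- "phantom"
  out
}

#' Generate a complete phantom
#'
#' Convenience wrapper: [generate_centerlines()] +
#' [decorate_and_render()].
#'
#' @param spec A [phantom_spec()], or arguments forwarded to it.
#' @param ... Passed to [phantom_spec()] when `spec` is missing.
#' @return A `phantom`, see [decorate_and_render()].
#' @examples
#' ph <- phantom(phantom_spec(volume_shape = c(32, 48, 48), n_fibers = 1,
#'                            fiber_radius = 40, seed = 7))
#' nrow(ph$particles)
#' @export
phantom <- function(spec = NULL, ...) {
  if (is.null(spec)) spec <- phantom_spec(...)
  decorate_and_render(spec)
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d fiber(s), %d particle(s) (%d background)\n",
              x$spec$n_fibers, nrow(x$particles),
              sum(x$particles$fiber == 0L)))
  print(x$volume)
  invisible(x)
}

#' Split a phantom into even/odd half-volumes
#'
#' Partitions the particles into two disjoint halves (seeded random
#' alternation) and renders each independently, emulating reconstructions
#' from even and odd tilt-series subsets. Optionally adds independent
#' Gaussian voxel noise to each half.
#'
#' @param ph A `phantom`.
#' @param seed Seed for the partition (default: derived from the phantom's
#'   own seed) and the voxel noise.
#' @param voxel_noise_sd Gaussian voxel noise SD added independently to
#'   each half (default 0 = none).
#' @return List with `even`, `odd` (both [vol3d()]) and `assignment`
#'   (1 or 2 per particle).
#' @export
split_even_odd <- function(ph, seed = NULL, voxel_noise_sd = 0) {
  stopifnot(inherits(ph, "phantom"))
  n <- nrow(ph$particles)
  if (n < 2L) stop("need at least 2 particles to split", call. = FALSE)
  if (is.null(seed)) seed <- derive_seed(ph$spec$seed, 30000L)
  set.seed(seed)
  ord <- sample.int(n)
  assignment <- integer(n)
  assignment[ord] <- rep_len(c(1L, 2L), n)
  coords <- cbind(ph$particles$z_nm, ph$particles$y_nm, ph$particles$x_nm)
  even <- render_particles(coords[assignment == 1L, , drop = FALSE], ph$spec)
  odd <- render_particles(coords[assignment == 2L, , drop = FALSE], ph$spec)
  if (voxel_noise_sd > 0) {
    set.seed(derive_seed(seed, 1L))
    even$data <- even$data + array(stats::rnorm(length(even$data),
                                                sd = voxel_noise_sd),
                                   dim(even$data))
    set.seed(derive_seed(seed, 2L))
    odd$data <- odd$data + array(stats::rnorm(length(odd$data),
                                              sd = voxel_noise_sd),
                                 dim(odd$data))
  }
  list(even = even, odd = odd, assignment = assignment)
}

#' Distance from points to the nearest centerline
#'
#' Exact point-to-polyline distance, used to verify phantom geometry
#' (every fiber particle lies within its fiber radius of a centerline).
#'
#' @param points `n x 3` matrix of `(z, y, x)` nm coordinates.
#' @param centerlines List of polylines as from [generate_centerlines()].
#' @return Numeric vector of distances in nm.
#' @export
dist_to_centerlines <- function(points, centerlines) {
  segs <- centerline_segments(centerlines)$segs
  if (is.null(segs)) return(rep(Inf, nrow(points)))
  out <- rep(Inf, nrow(points))
  for (s in seq_len(nrow(segs))) {
    a <- segs[s, 1:3]; b <- segs[s, 4:6]
    ab <- b - a
    len2 <- sum(ab^2)
    ap <- sweep(points, 2, a)
    t <- if (len2 > 0) pmin(pmax((ap %*% ab) / len2, 0), 1) else 0
    dd <- ap - t %*% t(ab)
    out <- pmin(out, sqrt(rowSums(dd^2)))
  }
  out
}

#' Write phantom ground truth to a directory
#'
#' Volume and truth mask as MRC, particles and centerlines as CSV
#' (`id, z_nm, y_nm, x_nm`), the spec as a flat `key=value` file.
#'
#' @param ph A `phantom`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(ph, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_mrc(ph$volume, file.path(dir, "volume.mrc"))
  tm <- ph$truth_mask
  write_mrc(vol3d(array(as.numeric(tm$data), dim(tm$data)),
                  tm$voxel_size, tm$origin),
            file.path(dir, "truth_mask.mrc"))
  write_particles_csv(ph$particles, file.path(dir, "particles.csv"))
  cl <- dplyr::bind_rows(purrr::imap(ph$centerlines, function(pts, f) {
    tibble::tibble(id = f, z_nm = pts[, 1], y_nm = pts[, 2], x_nm = pts[, 3])
  }))
  readr::write_csv(cl, file.path(dir, "centerlines.csv"))
  write_config(unclass(ph$spec), file.path(dir, "phantom_spec.cfg"))
  invisible(dir)
}
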