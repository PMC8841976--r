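make_ps <- function(coords, shape, voxel_size = 2) {
  particle_set(tibble::tibble(z_nm = coords[, 1], y_nm = coords[, 2],
                              x_nm = coords[, 3]),
               voxel_size = voxel_size, shape = shape)
}

test_that("a single particle yields an indicator ball of the radius", {
  ps <- make_ps(matrix(c(16, 16, 16), 1), shape = c(16, 16, 16))
  dm <- density_map(ps, radius = 50, k = 40)
  ctr <- oracle_centers(c(16, 16, 16), 2)
  inside <- sqrt(colSums((t(ctr) - c(16, 16, 16))^2)) <= 50
  expect_identical(as.numeric(dm$data), as.numeric(inside))
})

test_that("density is capped at k", {
  set.seed(2)
  coords <- matrix(rep(c(16, 16, 16), each = 60), 60) +
    matrix(runif(180, -4, 4), 60)
  ps <- make_ps(coords, shape = c(16, 16, 16))
  dm <- density_map(ps, radius = 20, k = 40)
  expect_equal(max(dm$data), 40)
})

test_that("density map is empty-input safe", {
  ps <- particle_set(tibble::tibble(z_nm = numeric(), y_nm = numeric(),
                                    x_nm = numeric()),
                     voxel_size = 2, shape = c(8, 8, 8))
  expect_error(density_map(ps, 10), "empty particle set")
  expect_error(sweep_radii(ps, c(10, 20)), "empty")
})

test_that("density map equals the all-pairs oracle voxel for voxel", {
  for (seed in 1:6) {
    inst <- random_instance(seed, shape = c(24, 24, 24), n = 300,
                            voxel_size = 2)
    ps <- make_ps(inst$coords, inst$shape, inst$voxel_size)
    dm <- density_map(ps, radius = 6, k = 40)
    expect_identical(dm$data,
                     oracle_density(inst$coords, inst$shape,
                                    inst$voxel_size, 6, 40))
  }
})

test_that("density support grows monotonically with radius and is bounded", {
  inst <- random_instance(99, shape = c(16, 16, 16), n = 80, voxel_size = 2)
  ps <- make_ps(inst$coords, inst$shape)
  prev <- NULL
  for (R in c(4, 8, 16)) {
    dm <- density_map(ps, R, k = 10)
    expect_true(all(dm$data >= 0 & dm$data <= 10))
    if (!is.null(prev)) expect_true(all(dm$data[prev] >= 1))
    prev <- dm$data >= 1
  }
})

test_that("density is invariant under rigid translation of particles and grid", {
  inst <- random_instance(3, shape = c(12, 12, 12), n = 50, voxel_size = 2)
  ps <- make_ps(inst$coords, inst$shape)
  dm0 <- density_map(ps, 8, k = 40)
  shift <- c(100, -40, 12.5)
  ps2 <- particle_set(tibble::tibble(z_nm = inst$coords[, 1] + shift[1],
                                     y_nm = inst$coords[, 2] + shift[2],
                                     x_nm = inst$coords[, 3] + shift[3]),
                      voxel_size = 2, shape = c(12, 12, 12), origin = shift)
  dm1 <- density_map(ps2, 8, k = 40)
  expect_identical(dm0$data, dm1$data)
})

test_that("sweep counts descend to the cluster count for two far clusters", {
  set.seed(4)
  a <- matrix(rep(c(30, 30, 30), each = 16), 16) + matrix(runif(48, -10, 10), 16)
  b <- matrix(rep(c(30, 100, 100), each = 16), 16) + matrix(runif(48, -10, 10), 16)
  radii <- c(2, 8, 16, 24, 30)
  ps <- make_ps(rbind(a, b), shape = c(32, 64, 64))
  sw <- sweep_radii(ps, radii = radii, k = 40)
  # oracle: brute-force pipeline at each radius
  oc <- sapply(radii, function(R) {
    dens <- oracle_density(rbind(a, b), c(32, 64, 64), 2, R, 40)
    thr <- oracle_isodata(dens)
    max(oracle_label(dens > thr, 26))
  })
  expect_equal(sw$n_objects, oc)
  expect_gt(sw$n_objects[1], 2)
  expect_equal(sw$n_objects[4], 2)
})

test_that("degenerate sweeps stay well-defined", {
  ps <- make_ps(matrix(c(16, 16, 16), 1), shape = c(16, 16, 16))
  sw1 <- sweep_radii(ps, radii = c(6, 10, 14, 18))
  expect_true(all(sw1$n_objects == 1))
  sw2 <- sweep_radii(ps, radii = 10)
  expect_equal(nrow(sw2), 1L)
  expect_error(sweep_radii(ps, radii = c(10, 5)), "increasing")
})

test_that("plateau detection follows the stated run rule", {
  sw <- tibble::tibble(radius_nm = seq(10, 100, 10),
                       n_objects = c(100, 60, 40, 40, 40, 25, 12, 12, 12, 3))
  pl <- detect_plateaus(sw, rel_tol = 0.05, min_span = 3)
  expect_equal(nrow(pl), 2L)
  expect_equal(pl$radius_mid, c(40, 80))       # run midpoints
  expect_equal(pl$radius_start, c(30, 70))     # run onsets (default radius_nm)
  expect_equal(pl$radius_nm, pl$radius_start)
  expect_equal(pl$n_objects, c(40, 12))
  # strictly decreasing counts: no stability anywhere
  sw2 <- tibble::tibble(radius_nm = seq(10, 60, 10),
                        n_objects = c(100, 80, 60, 40, 20, 10))
  expect_equal(nrow(detect_plateaus(sw2)), 0L)
  # constant counts: one plateau, midpoint at the middle radius
  sw3 <- tibble::tibble(radius_nm = seq(10, 50, 10), n_objects = rep(7, 5))
  pl3 <- detect_plateaus(sw3, representative = "midpoint")
  expect_equal(nrow(pl3), 1L)
  expect_equal(pl3$radius_nm, 30)
})

test_that("plateau radii are a subset of swept radii at the onset rule", {
  set.seed(11)
  sw <- tibble::tibble(radius_nm = seq(10, 200, 10),
                       n_objects = pmax(1, round(100 * exp(-(1:20) / 4))))
  pl <- detect_plateaus(sw)
  expect_true(all(pl$radius_nm %in% sw$radius_nm))
})

test_that("segmenting a single-fiber phantom at the saturation scale overlaps truth", {
  sp <- phantom_spec(volume_shape = c(64, 96, 96), n_fibers = 1,
                     fiber_radius = 60, fiber_length = 300,
                     noise_density = 0, seed = 21)
  ph <- phantom(sp)
  mask <- segment_fibers(ph$particles, radius = knn_radius(ph$particles))
  dice <- 2 * sum(mask$data & ph$truth_mask$data) /
    (sum(mask$data) + sum(ph$truth_mask$data))
  expect_gte(dice, 0.7)
})

test_that("segmentation errors on an all-zero density map", {
  # one particle placed off the voxel-centre lattice, radius below the
  # distance to any voxel centre
  ps <- make_ps(matrix(c(15.7, 15.3, 15.1), 1), shape = c(16, 16, 16))
  expect_error(segment_fibers(ps, radius = 0.05), "empty segmentation")
})

test_that("a single particle segments to a ball at the chosen radius", {
  ps <- make_ps(matrix(c(16, 16, 16), 1), shape = c(16, 16, 16))
  mask <- segment_fibers(ps, radius = 10)
  ctr <- oracle_centers(c(16, 16, 16), 2)
  inside <- sqrt(colSums((t(ctr) - c(16, 16, 16))^2)) <= 10
  expect_identical(as.logical(mask$data), as.logical(inside))
})

test_that("knn_radius reflects the neighbourhood saturation scale", {
  set.seed(31)
  n <- 600
  ext <- 300
  coords <- matrix(runif(3 * n, 0, ext), ncol = 3)
  ps <- make_ps(coords, shape = rep(ext / 2, 3), voxel_size = 2)
  lambda <- n / ext^3
  expected <- (3 * 40 / (4 * pi * lambda))^(1 / 3)
  expect_lt(abs(knn_radius(ps, 40) - expected) / expected, 0.15)
})
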