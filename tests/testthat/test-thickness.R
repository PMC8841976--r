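digital_ball <- function(r_vox, voxel_size = 2, pad = 3) {
  n <- 2 * (r_vox + pad) + 1
  ctr <- r_vox + pad + 1
  idx <- expand.grid(z = 1:n, y = 1:n, x = 1:n)
  arr <- array((idx$z - ctr)^2 + (idx$y - ctr)^2 + (idx$x - ctr)^2 <=
                 r_vox^2, c(n, n, n))
  vol3d(arr, voxel_size)
}

digital_cylinder <- function(r_vox, length_vox, voxel_size = 5, pad = 5) {
  n <- 2 * (r_vox + pad) + 1
  ctr <- r_vox + pad + 1
  cross <- outer((1:n) - ctr, (1:n) - ctr, function(a, b) a^2 + b^2 <= r_vox^2)
  arr <- array(FALSE, c(n, n, length_vox))
  for (x in seq_len(length_vox)) arr[, , x] <- cross
  vol3d(arr, voxel_size)
}

test_that("distance map follows the voxel-centre, faces-as-background convention", {
  arr <- array(FALSE, c(5, 5, 5))
  arr[3, 3, 3] <- TRUE
  dm <- distance_map(vol3d(arr, 2))
  expect_equal(dm$data[3, 3, 3], 2)
  expect_equal(sum(dm$data > 0), 1L)
  # a face voxel is one voxel from the outside
  arr2 <- array(TRUE, c(3, 3, 3))
  dm2 <- distance_map(vol3d(arr2, 2))
  expect_equal(dm2$data[1, 1, 1], 2)
  expect_equal(dm2$data[2, 2, 2], 4)
})

test_that("the distance map peak of a ball is its radius within half a voxel", {
  b <- digital_ball(10, voxel_size = 2)
  dm <- distance_map(b)
  expect_lt(abs(max(dm$data) - 10 * 2), 0.5 * 2)
})

test_that("distance maps agree voxel-exactly with the all-pairs oracle", {
  for (seed in 1:8) {
    set.seed(seed)
    arr <- array(runif(12^3) < 0.4, c(12, 12, 12))
    if (!any(arr)) next
    vs <- if (seed %% 2 == 0) c(4, 2, 2) else 2 # anisotropy covered too
    dm <- distance_map(vol3d(arr, vs))
    expect_equal(dm$data, oracle_distance(arr, vs), tolerance = 1e-12)
  }
})

test_that("a single voxel is its own skeleton", {
  arr <- array(FALSE, c(5, 5, 5))
  arr[3, 3, 3] <- TRUE
  sk <- skeletonize(vol3d(arr, 2), prune_len = 0)
  expect_identical(sk$data, arr)
})

test_that("a solid cylinder thins to its axis", {
  cyl <- digital_cylinder(8, 100, voxel_size = 5)
  sk <- skeletonize(cyl)
  w <- which(sk$data, arr.ind = TRUE)
  ctr <- 8 + 5 + 1
  expect_true(all(sqrt((w[, 1] - ctr)^2 + (w[, 2] - ctr)^2) <= 2))
  expect_gte(diff(range(w[, 3])) + 1, 0.8 * 100)
  expect_true(all(sk$data[cyl$data == FALSE] == FALSE)) # skeleton inside mask
})

test_that("disjoint components give disjoint skeletons", {
  arr <- array(FALSE, c(10, 10, 30))
  arr[4:6, 4:6, 2:12] <- TRUE
  arr[4:6, 4:6, 18:28] <- TRUE
  sk <- skeletonize(vol3d(arr, 2))
  w <- which(sk$data, arr.ind = TRUE)
  expect_true(all(w[, 3] <= 12 | w[, 3] >= 18))
  expect_true(any(w[, 3] <= 12) && any(w[, 3] >= 18))
})

test_that("local thickness recovers a cylinder radius within one voxel", {
  cyl <- digital_cylinder(15, 110, voxel_size = 5)
  th <- local_thickness(cyl, border_exclude = FALSE)
  expect_lt(abs(th$modal_radius_nm - 75), 5)
})

test_that("identical radii give zero spread and that exact mode", {
  # a straight one-voxel line: every interior skeleton voxel sees the same
  # lateral background distance
  arr <- array(FALSE, c(5, 5, 40))
  arr[3, 3, 2:39] <- TRUE
  th <- local_thickness(vol3d(arr, 2), border_exclude = FALSE, prune_len = 0)
  inner <- th$radii$radius_nm[th$radii$x %in% 3:38]
  expect_equal(stats::sd(inner), 0)
  ln <- local_thickness(vol3d(arr[, , 2:39, drop = FALSE] & TRUE, 2),
                        border_exclude = FALSE, prune_len = 0)
  expect_equal(ln$modal_radius_nm, 2)
})

test_that("every sampled radius equals the distance map at its voxel", {
  sp <- phantom_spec(volume_shape = c(48, 64, 64), n_fibers = 1,
                     fiber_radius = 40, fiber_length = 250,
                     noise_density = 0, seed = 3)
  ph <- phantom(sp)
  mask <- ph$truth_mask
  th <- local_thickness(mask)
  dm <- distance_map(mask)
  got <- mapply(function(z, y, x) dm$data[z, y, x],
                th$radii$z, th$radii$y, th$radii$x)
  expect_identical(unname(got), th$radii$radius_nm)
  expect_equal(th$se_nm, th$sd_nm / sqrt(th$n))
})

test_that("statistics scale linearly with voxel size", {
  cyl5 <- digital_cylinder(8, 60, voxel_size = 5)
  cyl10 <- digital_cylinder(8, 60, voxel_size = 10)
  t5 <- local_thickness(cyl5, bin_width = 5, border_exclude = FALSE)
  t10 <- local_thickness(cyl10, bin_width = 10, border_exclude = FALSE)
  expect_equal(t10$modal_radius_nm, 2 * t5$modal_radius_nm)
  expect_equal(t10$sd_nm, 2 * t5$sd_nm)
  expect_equal(t10$se_nm, 2 * t5$se_nm)
})

test_that("face-truncated skeleton voxels are excluded from the histogram", {
  # cylinder along z touches both z faces: every axis voxel's distance is
  # limited laterally, but near the faces it is limited by the section
  arr <- array(FALSE, c(30, 21, 21))
  cross <- outer((1:21) - 11, (1:21) - 11, function(a, b) a^2 + b^2 <= 8^2)
  for (z in 1:30) arr[z, , ] <- cross
  v <- vol3d(arr, 5)
  th <- local_thickness(v, border_exclude = TRUE)
  excl <- th$radii$excluded
  expect_true(any(excl))
  # excluded voxels are the ones near the z faces
  zface <- pmin(th$radii$z, 30 + 1 - th$radii$z) * 5
  expect_true(all(zface[excl] <= th$radii$radius_nm[excl] + 2.5))
  expect_equal(th$n, sum(!excl))
})

test_that("recovered modal radii increase with true fiber radius", {
  modes <- sapply(c(50, 75, 100), function(r) {
    sp <- phantom_spec(volume_shape = c(96, 128, 128), n_fibers = 1,
                       fiber_radius = r, fiber_length = 400,
                       persistence = 1, noise_density = 0, seed = 10)
    ph <- phantom(sp)
    local_thickness(ph$truth_mask, bin_width = 10,
                    prune_len = "adaptive")$modal_radius_nm
  })
  expect_true(all(diff(modes) > 0))
})

test_that("radius_report doubles modes into diameters and orders rows", {
  rp <- radius_report(data.frame(modal_radius_nm = 75))
  expect_equal(rp$diameter_nm, 150)
  sp <- phantom_spec(volume_shape = c(32, 48, 48), n_fibers = 1,
                     fiber_radius = 30, fiber_length = 150,
                     noise_density = 0, seed = 2)
  ph <- phantom(sp)
  t1 <- local_thickness(ph$truth_mask)
  t1$segmentation_radius_nm <- 60
  t2 <- local_thickness(ph$truth_mask, bin_width = 10)
  t2$segmentation_radius_nm <- 40
  rp2 <- radius_report(list(t1, t2), labels = c("b", "a"))
  expect_equal(rp2$label, c("a", "b")) # ordered by segmentation radius
  expect_equal(rp2$diameter_nm, 2 * rp2$modal_radius_nm)
})
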