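test_that("phantom_spec validates fields", {
  expect_error(phantom_spec(step_length = 0), "step_length")
  expect_error(phantom_spec(persistence = 1.2), "persistence")
  expect_error(phantom_spec(fiber_radius = -5), "fiber_radius")
  expect_error(phantom_spec(volume_shape = c(0, 10, 10)), "positive")
  expect_error(phantom_spec(label_density = -1), "densities")
})

test_that("no fibers means no centerlines", {
  sp <- phantom_spec(n_fibers = 0, volume_shape = c(16, 16, 16))
  expect_identical(generate_centerlines(sp), list())
})

test_that("persistence 1 gives straight centerlines", {
  sp <- phantom_spec(volume_shape = c(64, 64, 64), n_fibers = 3,
                     persistence = 1, min_separation = 0, seed = 4)
  for (pts in generate_centerlines(sp)) {
    if (nrow(pts) < 3) next
    d <- diff(pts)
    d <- d / sqrt(rowSums(d^2))
    cosines <- rowSums(d[-nrow(d), , drop = FALSE] * d[-1, , drop = FALSE])
    expect_equal(cosines, rep(1, length(cosines)), tolerance = 1e-12)
  }
})

test_that("persistence 0 gives uncorrelated step directions", {
  # Monte-Carlo oracle: cosines of independent uniform directions have
  # mean 0 and variance 1/3
  sp <- phantom_spec(volume_shape = c(64, 64, 64), voxel_size = 400,
                     n_fibers = 8, fiber_length = 2e5, step_length = 40,
                     persistence = 0, min_separation = 0, seed = 10)
  cl <- generate_centerlines(sp)
  cosines <- unlist(lapply(cl, function(pts) {
    if (nrow(pts) < 3) return(NULL)
    d <- diff(pts)
    d <- d / sqrt(rowSums(d^2))
    rowSums(d[-nrow(d), , drop = FALSE] * d[-1, , drop = FALSE])
  }))
  expect_gt(length(cosines), 5000)
  expect_lt(abs(mean(cosines)), 3 * stats::sd(cosines) / sqrt(length(cosines)))
})

test_that("centerline points are spaced step_length apart and stay in the box", {
  sp <- phantom_spec(volume_shape = c(48, 64, 64), n_fibers = 3, seed = 6)
  ext <- sp$volume_shape * sp$voxel_size
  for (pts in generate_centerlines(sp)) {
    steps <- sqrt(rowSums(diff(pts)^2))
    expect_equal(steps, rep(sp$step_length, length(steps)), tolerance = 1e-9)
    expect_true(all(pts >= 0 & pts <= rep(ext, each = nrow(pts))))
  }
})

test_that("phantoms are bit-identical for a fixed spec and seed", {
  sp <- phantom_spec(volume_shape = c(32, 48, 48), n_fibers = 2,
                     fiber_radius = 30, fiber_length = 200, seed = 12)
  a <- phantom(sp)
  b <- phantom(sp)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(as.data.frame(a$particles), as.data.frame(b$particles))
  expect_identical(a$truth_mask$data, b$truth_mask$data)
})

test_that("every fiber particle lies within the fiber radius of a centerline", {
  sp <- phantom_spec(volume_shape = c(48, 64, 64), n_fibers = 3,
                     fiber_radius = c(30, 40, 50), fiber_length = 250,
                     noise_density = 0, seed = 13)
  ph <- phantom(sp)
  pts <- cbind(ph$particles$z_nm, ph$particles$y_nm, ph$particles$x_nm)
  d <- dist_to_centerlines(pts, ph$centerlines)
  expect_true(all(d <= max(sp$fiber_radius) + 1e-9))
  # per-fiber check with each fiber's own radius
  for (f in seq_len(3)) {
    sel <- ph$particles$fiber == f
    if (!any(sel)) next
    df <- dist_to_centerlines(pts[sel, , drop = FALSE],
                              ph$centerlines[f])
    expect_true(all(df <= sp$fiber_radius[f] + 1e-9))
  }
})

test_that("with no background noise every particle is inside the truth mask tube", {
  sp <- phantom_spec(volume_shape = c(48, 64, 64), n_fibers = 2,
                     fiber_radius = 40, fiber_length = 250,
                     noise_density = 0, seed = 14)
  ph <- phantom(sp)
  d <- dist_to_centerlines(cbind(ph$particles$z_nm, ph$particles$y_nm,
                                 ph$particles$x_nm), ph$centerlines)
  expect_true(all(d <= 40))
  expect_true(all(ph$particles$fiber > 0))
})

test_that("zero densities render an empty phantom", {
  sp <- phantom_spec(volume_shape = c(16, 16, 16), n_fibers = 1,
                     fiber_radius = 20, fiber_length = 40,
                     label_density = 0, noise_density = 0, seed = 1)
  ph <- phantom(sp)
  expect_equal(nrow(ph$particles), 0L)
  expect_true(all(ph$volume$data == 0))
})

test_that("rendered mass equals particle count times the blob integral", {
  sp <- phantom_spec(volume_shape = c(48, 48, 48), n_fibers = 1,
                     fiber_radius = 30, fiber_length = 100,
                     label_density = 3e-5, noise_density = 0, seed = 15)
  ph <- phantom(sp)
  kern <- chromothick:::blob_kernel(sp)
  expect_lt(abs(sum(ph$volume$data) -
                nrow(ph$particles) * sum(kern$weights)) /
            (nrow(ph$particles) * sum(kern$weights)), 1e-6)
})

test_that("fiber particle counts follow the analytic Poisson mean", {
  # one straight fiber far from the borders
  line <- matrix(c(150, 150, 100, 150, 150, 1100), 2, 3, byrow = TRUE)
  lambda <- 2e-5
  counts <- sapply(1:200, function(s) {
    sp <- phantom_spec(volume_shape = c(38, 38, 150), voxel_size = 8,
                       n_fibers = 1, fiber_radius = 75,
                       label_density = lambda, noise_density = 0,
                       particle_radius = 6, seed = s)
    nrow(decorate_and_render(sp, list(line))$particles)
  })
  mu <- lambda * pi * 75^2 * 1000
  se <- sqrt(mu / 200) # Poisson SD of the mean of 200 draws
  expect_lt(abs(mean(counts) - mu), 3 * se)
})

test_that("even/odd splitting partitions the particles and sums linearly", {
  sp <- phantom_spec(volume_shape = c(32, 48, 48), n_fibers = 1,
                     fiber_radius = 30, fiber_length = 200, seed = 16)
  ph <- phantom(sp)
  h <- split_even_odd(ph)
  expect_setequal(h$assignment, c(1L, 2L))
  expect_equal(sum(h$assignment == 1L), ceiling(nrow(ph$particles) / 2))
  expect_identical(h$even$data + h$odd$data, ph$volume$data)
  # two particles: one in each half
  sp2 <- phantom_spec(volume_shape = c(16, 16, 16), n_fibers = 0,
                      noise_density = 2 / (64^3), seed = 30)
  repeat {
    ph2 <- phantom(sp2)
    if (nrow(ph2$particles) == 2L) break
    sp2$seed <- sp2$seed + 1L
  }
  h2 <- split_even_odd(ph2)
  expect_equal(sort(h2$assignment), c(1L, 2L))
})

test_that("voxel noise in the halves lowers high-frequency FSC", {
  sp <- phantom_spec(volume_shape = c(48, 48, 48), voxel_size = 3,
                     n_fibers = 2, fiber_radius = 30, fiber_length = 200,
                     min_separation = 80, seed = 17)
  ph <- phantom(sp)
  h0 <- split_even_odd(ph)
  h1 <- split_even_odd(ph, voxel_noise_sd = 50)
  c0 <- fsc_curve(h0$even, h0$odd)
  c1 <- fsc_curve(h1$even, h1$odd)
  expect_lt(mean(c1$fsc), mean(c0$fsc))
})

test_that("phantom ground truth is written to standard text and MRC formats", {
  sp <- phantom_spec(volume_shape = c(16, 24, 24), n_fibers = 1,
                     fiber_radius = 20, fiber_length = 80, seed = 18)
  ph <- phantom(sp)
  dir <- tempfile()
  write_phantom(ph, dir)
  expect_true(all(file.exists(file.path(dir,
    c("volume.mrc", "truth_mask.mrc", "particles.csv", "centerlines.csv",
      "phantom_spec.cfg")))))
  v <- read_mrc(file.path(dir, "volume.mrc"))
  expect_equal(v$data, ph$volume$data, tolerance = 1e-6)
  cfg <- read_config(file.path(dir, "phantom_spec.cfg"))
  expect_equal(cfg$fiber_radius, sp$fiber_radius)
  unlink(dir, recursive = TRUE)
})
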