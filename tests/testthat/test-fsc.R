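noise_vol <- function(seed, n = 32, vs = 2) {
  set.seed(seed)
  vol3d(array(stats::rnorm(n^3), c(n, n, n)), vs)
}

test_that("identical halves correlate perfectly in every shell", {
  a <- noise_vol(1)
  cc <- fsc_curve(a, a)
  expect_true(all(abs(cc$fsc - 1) < 1e-10))
  expect_true(all(diff(cc$freq_per_nm) > 0))
  expect_true(all(cc$n_voxels >= 1))
})

test_that("a sign flip gives FSC -1 everywhere", {
  a <- noise_vol(2)
  b <- vol3d(-a$data, a$voxel_size)
  cc <- fsc_curve(a, b)
  expect_true(all(abs(cc$fsc + 1) < 1e-10))
})

test_that("the curve is symmetric in its arguments and scale invariant", {
  a <- noise_vol(3)
  b <- noise_vol(4)
  c_ab <- fsc_curve(a, b)
  c_ba <- fsc_curve(b, a)
  expect_identical(c_ab$fsc, c_ba$fsc)
  b2 <- vol3d(b$data * 7.3, b$voxel_size)
  c_s <- fsc_curve(a, b2)
  expect_true(all(abs(c_s$fsc - c_ab$fsc) < 1e-10))
})

test_that("mismatched or constant inputs are rejected", {
  a <- noise_vol(5)
  expect_error(fsc_curve(a, noise_vol(6, n = 16)), "shape")
  expect_error(fsc_curve(a, noise_vol(6, vs = 3)), "voxel size")
  expect_error(fsc_curve(a, vol3d(array(1, dim(a$data)), 2)), "constant")
})

test_that("independent white noise stays inside the 3/sqrt(n) null band", {
  a <- noise_vol(7, n = 64)
  b <- noise_vol(8, n = 64)
  cc <- fsc_curve(a, b)
  frac <- mean(abs(cc$fsc) <= 3 / sqrt(cc$n_voxels))
  expect_gte(frac, 0.95)
})

test_that("resolution crossing is located by linear interpolation", {
  cv <- tibble::tibble(freq_per_nm = c(0.10, 0.12), fsc = c(0.5, 0.0),
                       n_voxels = c(100L, 100L))
  class(cv) <- c("fsc_curve", class(cv))
  r <- resolution_at(cv, 0.143)
  expect_equal(r$resolution_nm, 1 / (0.10 + 0.02 * (0.5 - 0.143) / 0.5),
               tolerance = 1e-12)
  expect_equal(r$flag, "ok")
})

test_that("curves that never cross are flagged rather than silent", {
  a <- noise_vol(9)
  hi <- fsc_curve(a, a)
  r1 <- resolution_at(hi)
  expect_equal(r1$flag, "nyquist_limited")
  expect_equal(r1$resolution_nm, 1 / max(hi$freq_per_nm))
  lo <- fsc_curve(noise_vol(10, n = 64), noise_vol(11, n = 64))
  r2 <- resolution_at(lo, criterion = 0.9)
  expect_equal(r2$flag, "below_criterion")
  expect_equal(r2$resolution_nm, 1 / lo$freq_per_nm[1])
})

test_that("band-limited half-volumes recover the cutoff within one shell", {
  sp <- phantom_spec(volume_shape = c(64, 64, 64), voxel_size = 3,
                     n_fibers = 2, fiber_radius = 40, fiber_length = 300,
                     min_separation = 60, seed = 8)
  ph <- phantom(sp)
  lp <- lowpass_volume(ph$volume, 9)
  s <- stats::sd(lp$data)
  ha <- lp
  set.seed(21)
  ha$data <- ha$data + array(stats::rnorm(length(lp$data), sd = 0.2 * s),
                             dim(lp$data))
  hb <- lp
  set.seed(22)
  hb$data <- hb$data + array(stats::rnorm(length(lp$data), sd = 0.2 * s),
                             dim(lp$data))
  cc <- fsc_curve(ha, hb)
  r <- resolution_at(cc, 0.143)
  expect_equal(r$flag, "ok")
  shell <- diff(cc$freq_per_nm[1:2])
  f9 <- 1 / 9
  expect_lte(abs(1 / r$resolution_nm - f9), shell + 1e-12)
})

test_that("anisotropic voxels honor physical frequency up to the right Nyquist", {
  set.seed(12)
  v <- vol3d(array(rnorm(32 * 32 * 16), c(32, 32, 16)), c(2, 2, 4))
  cc <- fsc_curve(v, v)
  # shells stop at the Nyquist of the coarsest axis (1 / (2 x 4 nm))
  expect_lte(max(cc$freq_per_nm), 1 / 8 + diff(cc$freq_per_nm[1:2]))
  expect_true(all(abs(cc$fsc - 1) < 1e-10))
})
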