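test_that("octahedral shear strain has the right analytic values", {
  dims <- c(10, 10, 10)
  mask <- array(TRUE, dims)
  # uniform translation: rigid motion has no strain
  u <- array(0 + 0i, c(dims, 3))
  u[, , , 1] <- 3 + 2i
  u[, , , 2] <- -1
  f <- displacement_field(u, 50, 2, mask)
  expect_true(all(octahedral_shear_strain(f) == 0))
  # pure simple shear u_x = gamma * y: gamma_oct = (2/3) sqrt(6) (gamma/2)
  gam <- 1e-3
  y_um <- ((1:dims[2]) - 1) * 2e3
  u <- array(0 + 0i, c(dims, 3))
  u[, , , 1] <- rep(gam * y_um, each = dims[1])
  f <- displacement_field(u, 50, 2, mask)
  g <- octahedral_shear_strain(f)
  expected <- (2 / 3) * sqrt(6) * gam / 2
  expect_equal(unname(g[5, 5, 5]), expected, tolerance = 1e-10)
  # linearity: doubling the field doubles the strain
  f2 <- displacement_field(2 * u, 50, 2, mask)
  expect_equal(octahedral_shear_strain(f2), 2 * g, tolerance = 1e-12)
  # mask thinner than the stencil
  thin <- array(FALSE, dims); thin[, , 5] <- TRUE
  expect_error(octahedral_shear_strain(
    displacement_field(u, 50, 2, thin)), "stencil")
})

test_that("OSS-SNR of pure noise is ~1 and the gate behaves", {
  dims <- c(24, 24, 24)  # ~1.4e4 voxels
  mask <- array(TRUE, dims)
  set.seed(42)
  u <- array(complex(real = rnorm(prod(dims) * 3, 0, 0.5),
                     imaginary = rnorm(prod(dims) * 3, 0, 0.5)),
             c(dims, 3))
  f <- displacement_field(u, 50, 2, mask, noise_sd = 0.5)
  rep <- oss_snr(f)
  expect_lt(abs(rep$oss_snr - 1), 0.1)
  expect_false(rep$pass)
  # noiseless field: capped sentinel, pass
  clean <- analytic_plane_wave(c(10, 10, 20))
  rep0 <- oss_snr(clean)
  expect_true(rep0$pass)
  expect_gte(rep0$oss_snr, 1e6)
  # monotonicity in sigma
  snrs <- vapply(c(0.05, 0.2, 0.8), function(s)
    oss_snr(add_noise(clean, s, seed = 1), noise_sd = s)$oss_snr, numeric(1))
  expect_true(all(diff(snrs) < 0))
  # scale invariance: scaling field and noise SD together
  big <- displacement_field(clean$u * 10, 50, 2, clean$mask, noise_sd = 1)
  small <- displacement_field(clean$u, 50, 2, clean$mask, noise_sd = 0.1)
  expect_equal(oss_snr(big)$oss_snr, oss_snr(small)$oss_snr,
               tolerance = 1e-10)
})

test_that("noise calibration hits the OSS-SNR target and gates a cohort", {
  mf <- slab_modulus(c(12, 12, 24))
  clean <- simulate_waves(mf, excitation = x_polarized,
                          boundary = slab_boundary)
  sd5 <- calibrate_noise_sd(clean, 5)
  got <- oss_snr(add_noise(clean, sd5, seed = 3))$oss_snr
  expect_lt(abs(got - 5) / 5, 0.15)
  # half a cohort at target 2, half at target 6: exactly the latter passes
  sd2 <- calibrate_noise_sd(clean, 2)
  sd6 <- calibrate_noise_sd(clean, 6)
  passes <- vapply(1:8, function(s) {
    sigma <- if (s <= 4) sd2 else sd6
    oss_snr(add_noise(clean, sigma, seed = s))$pass
  }, logical(1))
  expect_equal(passes, rep(c(FALSE, TRUE), each = 4))
})
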