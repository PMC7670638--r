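test_that("plane-wave wavelength matches the dispersion relation", {
  mf <- slab_modulus(c(12, 12, 36), 2, gp = 2.6, gpp = 0)
  f <- simulate_waves(mf, excitation = x_polarized, boundary = slab_boundary)
  expect_lte(f$solver$residual, 1e-8)
  lam <- fit_wavelength(f)
  expect_lt(abs(lam - 32.25) / 32.25, 0.05)  # c = sqrt(mu/rho) = 1.612 m/s
})

test_that("viscoelastic amplitude decay matches Im(k)", {
  gs <- 2 + 0.8i
  mf <- slab_modulus(c(12, 12, 36), 2, gp = Re(gs), gpp = Im(gs))
  f <- simulate_waves(mf, excitation = x_polarized, boundary = slab_boundary)
  dims <- dim(f$mask)
  zr <- 4:(dims[3] - 4)
  amp <- Mod(f$u[6, 6, zr, 1])
  z_mm <- zr * f$spacing
  dec <- -unname(coef(lm(log(amp) ~ z_mm))[2])  # per mm
  k <- 2 * pi * 50 * sqrt(1000 / (gs * 1e3))
  expect_lt(abs(dec - (-Im(k) / 1000)) / (-Im(k) / 1000), 0.05)
})

test_that("zero excitation yields an identically zero field", {
  mf <- slab_modulus(c(8, 8, 12))
  f <- simulate_waves(mf, excitation = list(amplitude = c(0, 0, 0)))
  expect_true(all(f$u == 0))
})

test_that("viscous loss strictly reduces total field energy", {
  dims <- c(10, 10, 24)
  elastic <- simulate_waves(slab_modulus(dims, gp = 2.6, gpp = 0),
                            excitation = x_polarized,
                            boundary = slab_boundary)
  viscous <- simulate_waves(slab_modulus(dims, gp = 2.6, gpp = 0.9),
                            excitation = x_polarized,
                            boundary = slab_boundary)
  expect_lt(sum(Mod(viscous$u)^2), sum(Mod(elastic$u)^2))
})

test_that("grid refinement changes the interior field by <= 2% RMS", {
  # smooth viscoelastic phantom at ~32 points per wavelength: damping keeps
  # the (h-dependent) first-order absorbing-boundary reflection from
  # imprinting a resolution-dependent standing-wave ripple
  coarse <- simulate_waves(slab_modulus(c(10, 10, 24), spacing = 1,
                                        gp = 2.6, gpp = 1.0),
                           excitation = x_polarized,
                           boundary = slab_boundary)
  fine <- simulate_waves(slab_modulus(c(19, 19, 47), spacing = 0.5,
                                      gp = 2.6, gpp = 1.0),
                         excitation = x_polarized, boundary = slab_boundary)
  # fine voxel (2i-1) centres coincide with coarse voxel i centres
  interior <- 3:22
  uc <- coarse$u[5, 5, interior, 1]
  uf <- fine$u[9, 9, 2 * interior - 1, 1]
  rel <- sqrt(mean(Mod(uc - uf)^2)) / sqrt(mean(Mod(uf)^2))
  expect_lt(rel, 0.02)
})

test_that("noise injection is seeded, recorded, and sized as requested", {
  mf <- slab_modulus(c(10, 10, 20))
  f <- simulate_waves(mf, excitation = x_polarized, boundary = slab_boundary)
  expect_identical(add_noise(f, 0), f)
  n1 <- add_noise(f, 0.3, seed = 5)
  n2 <- add_noise(f, 0.3, seed = 5)
  expect_identical(n1$u, n2$u)
  expect_equal(n1$noise_sd, 0.3)
  expect_false(identical(add_noise(f, 0.3, seed = 6)$u, n1$u))
  # empirical SD of the injected noise
  d <- (n1$u - f$u)[rep(f$mask, 3)]
  expect_lt(abs(sd(Re(d)) - 0.3) / 0.3, 0.05)
  expect_lt(abs(sd(Im(d)) - 0.3) / 0.3, 0.05)
})

test_that("phase-offset sampling and harmonic extraction are exact inverses", {
  f <- analytic_plane_wave(c(6, 6, 16))
  s4 <- sample_phase_offsets(f, 4)
  expect_lt(max(Mod(harmonic_fit(s4) - f$u)), 1e-10)
  # a constant offset lives in the zero-frequency bin and drops out
  expect_lt(max(Mod(harmonic_fit(s4 + 3.7) - f$u)), 1e-10)
  # n = 8 and n = 4 extract the identical harmonic of a pure tone
  s8 <- sample_phase_offsets(f, 8)
  expect_lt(max(Mod(harmonic_fit(s8) - harmonic_fit(s4))), 1e-10)
  expect_error(sample_phase_offsets(f, 2), "unrecoverable")
})
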