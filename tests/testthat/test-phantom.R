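test_that("mu/xi <-> modulus conversion matches its closed form and oracle", {
  # elastic limit: a = 1 forces G' = mu
  g <- mu_xi_to_modulus(3.0, 0)
  expect_equal(g$gp, 3.0)
  expect_equal(g$gpp, 0)
  # frozen values from a uniroot oracle on the forward formulas
  g <- mu_xi_to_modulus(2.360680, 0.25)
  expect_equal(g$gp, 2.0, tolerance = 1e-6)
  expect_equal(g$gpp, 1.0, tolerance = 1e-6)
  g <- mu_xi_to_modulus(2.62, 0.205)
  expect_equal(g$gp, 2.3335593, tolerance = 1e-6)
  expect_equal(g$gpp, 0.9567593, tolerance = 1e-6)
  # round trip over the physiological grid, <= 1e-10 relative
  mu <- seq(0.5, 6, length.out = 23)
  xi <- seq(0, 0.45, length.out = 19)
  grid <- expand.grid(mu = mu, xi = xi)
  g <- mu_xi_to_modulus(grid$mu, grid$xi)
  expect_lt(max(abs(compute_mu(g$gp, g$gpp) - grid$mu) / grid$mu), 1e-10)
  expect_lt(max(abs(compute_xi(g$gp, g$gpp) - grid$xi)), 1e-10)
  # domain errors
  expect_error(mu_xi_to_modulus(-1, 0.1), "mu")
  expect_error(mu_xi_to_modulus(2, 0.5), "xi")
})

test_that("build_phantom paints geometry deterministically", {
  shape <- c(24, 24, 24)
  brain <- geom_ellipsoid(rep(23, 3), rep(23, 3))
  bg <- region_spec(1, "bg", brain, mu_mean = 3, xi_mean = 0.2)
  # degenerate one-region case: ellipsoid filling the mask
  ph <- build_phantom(phantom_spec(shape, 2, brain, bg))
  expect_true(all(ph$labels[ph$mask] == 1L))
  expect_true(all(ph$labels[!ph$mask] == 0L))
  # two disjoint ellipsoids: voxel counts vs analytic volume within one
  # voxel-surface layer
  e1 <- geom_ellipsoid(c(20, 20, 16), c(8, 10, 6))
  e2 <- geom_ellipsoid(c(30, 30, 30), c(6, 6, 6))
  r1 <- region_spec(2, "r1", e1, 4, 0.1)
  r2 <- region_spec(3, "r2", e2, 2, 0.3)
  ph <- build_phantom(phantom_spec(shape, 2, brain, bg, list(r1, r2)))
  vol_vox <- function(a, b, c) 4 / 3 * pi * a * b * c / 8  # voxel = 8 mm^3
  surf_vox <- function(a, b, c) {  # ellipsoid surface area / face area
    p <- 1.6075
    4 * pi * ((a^p * b^p + a^p * c^p + b^p * c^p) / 3)^(1 / p) / 4
  }
  n1 <- sum(ph$labels == 2)
  n2 <- sum(ph$labels == 3)
  expect_lt(abs(n1 - vol_vox(8, 10, 6)), surf_vox(8, 10, 6))
  expect_lt(abs(n2 - vol_vox(6, 6, 6)), surf_vox(6, 6, 6))
  # determinism
  ph2 <- build_phantom(phantom_spec(shape, 2, brain, bg, list(r1, r2)))
  expect_identical(ph$labels, ph2$labels)
  # region outside the mask errors with its name
  bad <- region_spec(4, "runaway", geom_ellipsoid(c(46, 46, 46), c(4, 4, 4)),
                     3, 0.2)
  expect_error(build_phantom(phantom_spec(shape, 2, brain, bg, list(bad))),
               "runaway")
})

test_that("default six-region phantom matches the frozen label histogram", {
  ph <- build_phantom(phantom_sgm6())
  h <- table(ph$labels[ph$labels > 0])
  golden <- read.csv(test_path("fixtures", "sgm6_label_histogram.csv"))
  expect_equal(as.integer(names(h)), golden$label)
  expect_equal(as.integer(h), golden$n_voxels)
})

test_that("cohort sampling honours means, offsets, and the seed contract", {
  spec <- phantom_two_compartment(shape = c(12, 12, 12), sd_scale = 0)
  co <- sample_cohort(spec, 3, seed = 11)
  # zero SD, no offsets: every subject identical to the region means
  expect_equal(unique(co$truth$mu[co$truth$region == "WM"]), 2.95)
  expect_equal(unique(co$truth$xi[co$truth$region == "CGM"]), 0.206)
  expect_equal(co$fields[[1]]$gp, co$fields[[3]]$gp)
  # same seed twice: identical cohort
  co2 <- sample_cohort(spec, 3, seed = 11)
  expect_identical(co$subjects, co2$subjects)
  expect_identical(co$fields[[2]]$gpp, co2$fields[[2]]$gpp)
  # distinct seeds differ
  spec_sd <- phantom_two_compartment(shape = c(12, 12, 12), sd_scale = 1)
  co3 <- sample_cohort(spec_sd, 3, seed = 12)
  co4 <- sample_cohort(spec_sd, 3, seed = 13)
  expect_false(identical(co3$truth$mu, co4$truth$mu))
  # sex offsets applied in the stated directions
  spec_sex <- phantom_two_compartment(shape = c(12, 12, 12), sd_scale = 0,
                                      sex_effects = TRUE)
  co5 <- sample_cohort(spec_sex, 20, seed = 14)
  wm <- co5$truth[co5$truth$region == "WM", ]
  sx <- co5$subjects$sex[wm$subject]
  expect_gt(mean(wm$mu[sx == "M"]), mean(wm$mu[sx == "F"]))  # males stiffer
  expect_gt(mean(wm$xi[sx == "F"]), mean(wm$xi[sx == "M"]))  # females higher xi
})

test_that("cohort moments converge to the population parameters", {
  # Monte-Carlo check on the WM compartment: n = 500 within 3 SE
  spec <- phantom_two_compartment(shape = c(8, 8, 8), sd_scale = 1)
  co <- sample_cohort(spec, 500, seed = 99)
  wm_mu <- co$truth$mu[co$truth$region == "WM"]
  se <- 0.18 / sqrt(500)
  expect_lt(abs(mean(wm_mu) - 2.95), 3 * se)
  expect_lt(abs(sd(wm_mu) - 0.18), 0.035)  # truncation shrinks SD slightly
})

test_that("region spec validation enforces physical bounds", {
  g <- geom_ellipsoid(c(0, 0, 0), c(5, 5, 5))
  expect_error(region_spec(1, "x", g, mu_mean = 1, xi_mean = 0.1, mu_sd = 0.5),
               "positive")
  expect_error(region_spec(1, "x", g, mu_mean = -1, xi_mean = 0.1))
  expect_error(phantom_spec(c(8, 8, 8), 2, g,
                            region_spec(1, "a", g, 3, 0.2),
                            list(region_spec(1, "b", g, 3, 0.2))),
               "unique")
})
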