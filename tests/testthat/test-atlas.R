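test_that("the template grid has the stated fixed geometry", {
  g <- template_grid()
  expect_identical(g$shape, c(91L, 109L, 91L))
  expect_equal(g$spacing, 2)
  expect_equal(abs(det(g$affine[1:3, 1:3]))^(1 / 3), 2)
})

test_that("resampling contracts: identity, pure shift, single interpolation", {
  dims <- c(12, 14, 10)
  set.seed(5)
  mu <- array(runif(prod(dims), 1, 4), dims)
  xi <- array(runif(prod(dims), 0.1, 0.3), dims)
  mask <- array(TRUE, dims)
  pm <- property_maps(mu, xi, mask, 2)
  grid <- list(shape = dims, spacing = 2, affine = pm$affine)
  # identity on the same grid returns the input bit-identically
  out <- resample_to_template(pm, diag(4), grid)
  expect_identical(out$mu, pm$mu)
  # translation by exactly one voxel: interior equals a shifted copy
  shift <- diag(4); shift[1, 4] <- 2  # +2 mm = one voxel along x
  out <- resample_to_template(pm, shift, grid)
  expect_equal(out$mu[2:dims[1], , ], pm$mu[1:(dims[1] - 1), , ],
               tolerance = 1e-12)
  # chain of two transforms equals their product applied once
  A <- diag(4); A[1:3, 4] <- c(2, -2, 0)
  B <- diag(4); B[1:3, 1:3] <- diag(c(1.1, 1, 0.9)); B[2, 4] <- 4
  out_chain <- resample_to_template(pm, list(B, A), grid)
  out_single <- resample_to_template(pm, B %*% A, grid)
  expect_equal(out_chain$mu, out_single$mu, tolerance = 1e-12)
  expect_identical(out_chain$mask, out_single$mask)
  # fully outside support errors
  far <- diag(4); far[1, 4] <- 1e4
  expect_error(resample_to_template(pm, far, grid), "outside")
})

test_that("affine transforms round-trip through text files", {
  M <- diag(4); M[1:3, 4] <- c(3, -7, 2); M[1, 2] <- 0.05
  tr <- affine_transform(M)
  path <- withr::local_tempfile(fileext = ".txt")
  write_affine(tr, path)
  tr2 <- read_affine(path)
  expect_equal(tr2$matrix, M, tolerance = 1e-12)
  expect_error(affine_transform(matrix(0, 4, 4)), "invertible")
})

test_that("estimate_affine recovers identity and a known transform", {
  fixed <- blob_volume()
  # moving == fixed: identity to a tenth of a voxel
  tr <- estimate_affine(fixed, fixed)
  expect_lt(max(abs(tr$matrix[1:3, 4])), 0.2)       # <= 0.1 voxel at 2 mm
  expect_lt(max(abs(tr$matrix[1:3, 1:3] - diag(3))), 5e-3)
  # known affine: 10 deg rotation, 5 mm shift, 5% scale
  M <- mreatlas:::params_to_affine(c(5, 0, 0, 0, 0, 10, log(1.05), 0, 0,
                                     0, 0, 0),
                                   center = c(27, 27, 27))
  grid <- list(shape = dim(fixed$data), spacing = 2, affine = fixed$affine)
  moving <- list(data = mreatlas:::resample_array(fixed$data, fixed$affine,
                                                  M, grid)$data,
                 affine = fixed$affine)
  est <- estimate_affine(moving, fixed)
  # landmark error of est vs the true inverse mapping, in voxels
  pts <- rbind(c(20, 20, 20, 1), c(34, 20, 30, 1), c(20, 34, 26, 1),
               c(28, 28, 40, 1))
  err <- sqrt(rowSums(((est$matrix %*% t(pts)) -
                       (solve(M) %*% t(pts)))[1:3, ]^2)) / 2
  expect_lt(mean(err), 0.5)
  # same recovery with noise at SNR 5, looser bound
  set.seed(9)
  noisy <- moving
  noisy$data <- noisy$data + rnorm(length(noisy$data),
                                   sd = sd(moving$data) / 5)
  est_n <- estimate_affine(noisy, fixed)
  err_n <- sqrt(rowSums(((est_n$matrix %*% t(pts)) -
                         (solve(M) %*% t(pts)))[1:3, ]^2)) / 2
  expect_lt(mean(err_n), 1.0)
})

test_that("atlas averaging follows sampling theory", {
  dims <- c(10, 10, 10)
  mask <- array(TRUE, dims)
  mk <- function(mu_val, xi_val = 0.2, msk = mask)
    property_maps(array(mu_val, dims), array(xi_val, dims), msk, 2)
  # N identical maps: atlas equals each input
  at <- build_atlas(list(mk(2.5), mk(2.5), mk(2.5)))
  expect_equal(at$mu_mean, mk(2.5)$mu)
  expect_true(all(at$coverage == 3))
  # two maps with values 2 and 4: mean 3, SD sqrt(2)
  at2 <- build_atlas(list(mk(2), mk(4)))
  expect_equal(unique(as.vector(at2$mu_mean)), 3)
  expect_equal(unique(as.vector(at2$mu_sd)), sqrt(2))
  # single subject: atlas equals that subject's map
  at1 <- build_atlas(list(mk(3.3)))
  expect_equal(at1$mu_mean, mk(3.3)$mu)
  # permutation invariance
  maps <- lapply(c(2, 3, 4, 6), mk)
  expect_equal(build_atlas(maps)$mu_mean,
               build_atlas(rev(maps))$mu_mean)
  # coverage modes: partial masks
  m2 <- mask; m2[1:3, , ] <- FALSE
  at3 <- build_atlas(list(mk(2), mk(4, msk = m2)), coverage_mode = "subject")
  expect_equal(at3$mu_mean[1, 1, 1], 2)     # only subject 1 covers
  expect_equal(at3$mu_mean[5, 5, 5], 3)
  at4 <- build_atlas(list(mk(2), mk(4, msk = m2)), coverage_mode = "template")
  expect_false(at4$mask[1, 1, 1])
  # 20-subject cohort check: atlas mask-mean within 1 between-subject SE
  set.seed(77)
  vals <- rnorm(20, 3, 0.3)
  at5 <- build_atlas(lapply(vals, mk))
  expect_lt(abs(mean(at5$mu_mean[at5$mask]) - mean(vals)), 1e-10)
  expect_lt(abs(mean(at5$mu_mean[at5$mask]) - 3), 0.3 / sqrt(20) * 3)
})
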