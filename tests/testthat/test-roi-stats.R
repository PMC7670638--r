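test_that("mask erosion and probabilistic thresholding are exact", {
  # 3x3x3 solid cube erodes to its centre voxel
  cube <- array(0L, c(5, 5, 5))
  cube[2:4, 2:4, 2:4] <- 1L
  m <- make_roi_masks(cube, "label", names = "cube")
  expect_equal(sum(m$cube), 1)
  expect_true(m$cube[3, 3, 3])
  # probabilistic threshold is inclusive at 0.20
  p <- array(0.1, c(3, 3, 3))
  p[1, 1, 1] <- 0.2
  p[2, 2, 2] <- 0.3
  pm <- make_roi_masks(list(roi = p), "probabilistic")
  expect_equal(sum(pm$roi), 2)
  expect_true(pm$roi[1, 1, 1] && pm$roi[2, 2, 2])
  # sphere: erosion equals a brute-force set-arithmetic oracle exactly
  dims <- c(15, 15, 15)
  idx <- arrayInd(seq_len(prod(dims)), dims)
  r2 <- rowSums((idx - 8)^2)
  sphere <- array(as.integer(r2 <= 25), dims)
  er <- make_roi_masks(sphere, "label", names = "s")$s
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  oracle <- vapply(seq_len(prod(dims)), function(v) {
    if (!sphere[v]) return(FALSE)
    all(vapply(1:6, function(k) {
      nb <- idx[v, ] + offs[k, ]
      all(nb >= 1 & nb <= dims) && sphere[nb[1], nb[2], nb[3]] == 1L
    }, logical(1)))
  }, logical(1))
  expect_identical(as.vector(er), oracle)
  # erosion emptying a region errors with its name
  thin <- array(0L, c(4, 4, 4))
  thin[2, , ] <- 1L
  expect_error(make_roi_masks(thin, "label", names = "sheet"), "sheet")
})

test_that("ROI means are mask-aware", {
  dims <- c(6, 6, 6)
  pmap <- property_maps(array(2.5, dims), array(0.2, dims),
                        array(TRUE, dims), 2)
  masks <- list(a = slice_sel(dims, 3, 1:3), b = slice_sel(dims, 3, 4:6))
  em <- extract_roi_means(pmap, masks)
  expect_equal(em$value[em$measure == "mu"], c(2.5, 2.5))
  # two-voxel mask with values 2 and 4 -> 3
  mu <- array(0, dims); mu[1, 1, 1] <- 2; mu[2, 1, 1] <- 4
  msk <- array(FALSE, dims); msk[1:2, 1, 1] <- TRUE
  pm2 <- property_maps(mu, mu * 0, msk, 2)
  em2 <- extract_roi_means(pm2, list(r = msk))
  expect_equal(em2$value[em2$measure == "mu"], 3)
  # empty region -> missing
  em3 <- extract_roi_means(pm2, list(z = array(FALSE, dims)))
  expect_true(all(is.na(em3$value)))
})

test_that("the mixed model reproduces F = t^2 on two balanced regions", {
  tab <- simulate_roi_table(n = 30, region_means = c(A = 3, B = 2.6),
                            Sigma = matrix(c(.04, .025, .025, .05), 2),
                            seed = 21)
  tab$sex <- "M"  # no sex term
  fit <- fit_mixed_model(tab, "mu")
  wide <- matrix(tab$value, ncol = 2, byrow = TRUE)
  tt <- t.test(wide[, 1] - wide[, 2])
  expect_equal(fit$tests$region$F, unname(tt$statistic)^2, tolerance = 1e-8)
  expect_equal(fit$tests$region$p, tt$p.value, tolerance = 1e-8)
  expect_equal(fit$tests$region$df2, unname(tt$parameter))
})

test_that("marginal means equal stratified raw means in the balanced case", {
  tab <- simulate_roi_table(n = 40, region_means = c(A = 3, B = 2.6, C = 2),
                            sex_effect = c(A = 0.1, B = 0, C = -0.05),
                            seed = 31)
  fit <- fit_mixed_model(tab, "mu")
  raw <- aggregate(value ~ region + sex, tab, mean)
  for (r in c("A", "B", "C")) {
    expect_equal(fit$marginal_means$male[fit$marginal_means$region == r],
                 raw$value[raw$region == r & raw$sex == "M"],
                 tolerance = 1e-6)
    expect_equal(fit$marginal_means$female[fit$marginal_means$region == r],
                 raw$value[raw$region == r & raw$sex == "F"],
                 tolerance = 1e-6)
  }
  # Bonferroni bookkeeping: R(R-1)/2 pairwise tests, p monotone in raw p
  expect_equal(sum(!is.na(fit$pairwise_p[upper.tri(fit$pairwise_p)])), 3)
  sw <- fit$sex_within_region
  expect_true(all(sw$p_adj >= sw$p_raw - 1e-15))
  expect_true(all(sw$p_adj <= 1))
})

test_that("the model handles missing entries through the observed subvector", {
  tab <- simulate_roi_table(n = 60, region_means = c(A = 3, B = 2.6, C = 2.2),
                            Sigma = diag(.04, 3) + .02, seed = 41)
  drop <- sample(nrow(tab), 25)
  tab_miss <- tab[-drop, ]
  fit <- fit_mixed_model(tab_miss, "mu")
  expect_true(fit$converged)
  expect_equal(fit$n_subjects, 60)
  mm <- fit$marginal_means
  expect_lt(max(abs(mm$average[match(c("A", "B", "C"), mm$region)] -
                    c(3, 2.6, 2.2))), 0.15)
  ev <- eigen(fit$Sigma, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
})

test_that("boxplot outlier removal follows the 1.5 IQR rule", {
  # normal-theory flag rate ~0.7% (0.3 - 1.2% band), n = 1000 rows
  tab <- simulate_roi_table(n = 500, region_means = c(A = 3, B = 2.5),
                            seed = 51)
  fit <- fit_mixed_model(tab, "mu")
  rm <- remove_outliers(tab, fit)
  rate <- rm$n_removed / nrow(tab)
  expect_gt(rate, 0.003)
  expect_lt(rate, 0.012)
  # no outliers -> unchanged
  tab2 <- simulate_roi_table(n = 20, region_means = c(A = 3, B = 2.5),
                             seed = 52)
  wide <- matrix(tab2$value, ncol = 2, byrow = TRUE)
  # force all residuals inside the whiskers by shrinking toward the mean
  tab2$value <- rep(colMeans(wide), 20) + 0.001 * (tab2$value - rep(colMeans(wide), 20))
  fit2 <- fit_mixed_model(tab2, "mu")
  rm2 <- remove_outliers(tab2, fit2)
  expect_equal(rm2$n_removed, 0)
  expect_identical(rm2$table, tab2)
  # a single gross outlier is removed exactly
  tab3 <- simulate_roi_table(n = 40, region_means = c(A = 3, B = 2.5),
                             seed = 53)
  bad_row <- which(tab3$subject == 7 & tab3$region == "A")
  tab3$value[bad_row] <- tab3$value[bad_row] + 10 * 0.2
  fit3 <- fit_mixed_model(tab3, "mu")
  rm3 <- remove_outliers(tab3, fit3)
  expect_equal(nrow(rm3$removed), 1)
  expect_equal(rm3$removed$subject, "7")
  expect_equal(rm3$removed$region, "A")
})

test_that("shapiro_wilk wraps the reference test with domain bounds", {
  w <- shapiro_wilk(qnorm(ppoints(50)))
  expect_gt(w$statistic, 0.99)
  set.seed(61)
  e <- shapiro_wilk(rexp(100))
  expect_lt(e$p, 0.01)
  expect_error(shapiro_wilk(c(1, 2)), "n")
})

test_that("study effects are absorbed by the study fixed effect", {
  tab <- simulate_roi_table(n = 60, region_means = c(A = 3, B = 2.5),
                            n_studies = 3, seed = 71)
  shift <- c(A = 0, B = 0.3, C = -0.2)[tab$study]
  tab$value <- tab$value + shift
  fit <- fit_mixed_model(tab, "mu")
  # marginal means use equal study weights: recover the unshifted means
  # up to the average shift ((0 + 0.3 - 0.2)/3)
  adj <- mean(c(0, 0.3, -0.2))
  expect_lt(max(abs(fit$marginal_means$average - (c(3, 2.5) + adj))), 0.08)
})
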