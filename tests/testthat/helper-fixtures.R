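# Shared test fixtures, built in code at test time.

# small rectangular slab phantom with a homogeneous modulus
slab_modulus <- function(dims = c(12, 12, 32), spacing = 2,
                         gp = 2.6, gpp = 0) {
  mask <- array(TRUE, dims)
  modulus_field(array(gp, dims), array(gpp, dims), mask, spacing)
}

# analytic plane shear wave travelling along +z, x-polarized, on a slab grid
analytic_plane_wave <- function(dims = c(10, 10, 36), spacing = 2,
                                gstar_kpa = 2 + 0.8i, rho = 1000, f = 50,
                                amplitude = 10) {
  k <- 2 * pi * f * sqrt(rho / (gstar_kpa * 1e3))  # rad/m, Im(k) < 0
  z <- (seq_len(dims[3]) - 1) * spacing * 1e-3
  u <- array(0 + 0i, c(dims, 3))
  wave <- amplitude * exp(-1i * k * z)
  u[, , , 1] <- rep(wave, each = dims[1] * dims[2])
  displacement_field(u, f, spacing, array(TRUE, dims))
}

# slab boundary set-up: plane excitation at zmin, absorbing far face,
# zero-flux side walls (mirror symmetry of an infinite plane wave)
slab_boundary <- c(xmin = "neumann", xmax = "neumann", ymin = "neumann",
                   ymax = "neumann", zmin = "neumann", zmax = "absorbing")

x_polarized <- list(amplitude = c(10 + 0i, 0, 0), face = "zmin")

# wavelength along z from the phase slope of the first component
fit_wavelength <- function(field, drop_ends = 3) {
  dims <- dim(field$mask)
  i <- max(1, floor(dims[1] / 2))
  j <- max(1, floor(dims[2] / 2))
  zr <- (1 + drop_ends):(dims[3] - drop_ends)
  ph <- Arg(field$u[i, j, zr, 1])
  for (t in 2:length(ph)) {
    while (ph[t] - ph[t - 1] > pi) ph[t] <- ph[t] - 2 * pi
    while (ph[t] - ph[t - 1] < -pi) ph[t] <- ph[t] + 2 * pi
  }
  z_mm <- zr * field$spacing
  k <- abs(unname(coef(lm(ph ~ z_mm))[2]))  # rad/mm
  2 * pi / k
}

# small two-slab phantom (soft lower half, stiff upper half along z)
two_slab_modulus <- function(dims = c(16, 16, 32), spacing = 2,
                             mu = c(2, 4), xi = c(0.1, 0.1)) {
  g1 <- mu_xi_to_modulus(mu[1], xi[1])
  g2 <- mu_xi_to_modulus(mu[2], xi[2])
  half <- dims[3] / 2
  gp <- array(g1$gp, dims); gp[, , (half + 1):dims[3]] <- g2$gp
  gpp <- array(g1$gpp, dims); gpp[, , (half + 1):dims[3]] <- g2$gpp
  modulus_field(gp, gpp, array(TRUE, dims), spacing)
}

# quick synthetic ROI table: n subjects x R regions, unstructured covariance
simulate_roi_table <- function(n = 40, region_means = c(A = 3, B = 2.5),
                               Sigma = NULL, sex_effect = NULL,
                               n_studies = 1, measure = "mu", seed = 1) {
  set.seed(seed)
  R <- length(region_means)
  if (is.null(Sigma)) Sigma <- diag(0.04, R)
  L <- chol(Sigma)
  sex <- rep(c("M", "F"), length.out = n)
  study <- LETTERS[rep(seq_len(n_studies), length.out = n)]
  rows <- list()
  for (s in seq_len(n)) {
    mu_s <- region_means
    if (!is.null(sex_effect) && sex[s] == "F") mu_s <- mu_s + sex_effect
    y <- mu_s + as.vector(t(L) %*% rnorm(R))
    rows[[s]] <- data.frame(subject = s, sex = sex[s], study = study[s],
                            region = names(region_means), measure = measure,
                            value = y, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# logical array selecting given indices along one axis
slice_sel <- function(dims, axis, idx) {
  sel <- array(FALSE, dims)
  ix <- lapply(dims, seq_len)
  ix[[axis]] <- idx
  sel[ix[[1]], ix[[2]], ix[[3]]] <- TRUE
  sel
}

# voxels of a mask touching its boundary (6-connected)
outer_layer <- function(mask) {
  er <- mask
  for (ax in 1:3) for (by in c(-1, 1)) {
    shifted <- array(FALSE, dim(mask))
    dims <- dim(mask)
    idx_src <- idx_dst <- lapply(dims, seq_len)
    if (by > 0) { idx_dst[[ax]] <- 2:dims[ax]; idx_src[[ax]] <- 1:(dims[ax]-1) }
    else { idx_dst[[ax]] <- 1:(dims[ax]-1); idx_src[[ax]] <- 2:dims[ax] }
    shifted[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      mask[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    er <- er & shifted
  }
  mask & !er
}

# blob image pair for registration tests: a few gaussian bumps in a volume
blob_volume <- function(dims = c(28, 28, 28), spacing = 2, seed = 7) {
  set.seed(seed)
  co <- lapply(dims, function(d) (seq_len(d) - 1) * spacing)
  vol <- array(0, dims)
  centers <- cbind(runif(5, 0.25, 0.75) * dims[1] * spacing,
                   runif(5, 0.25, 0.75) * dims[2] * spacing,
                   runif(5, 0.25, 0.75) * dims[3] * spacing)
  for (b in 1:5) {
    dx2 <- outer(outer((co[[1]] - centers[b, 1])^2,
                       (co[[2]] - centers[b, 2])^2, "+"),
                 (co[[3]] - centers[b, 3])^2, "+")
    vol <- vol + exp(-dx2 / (2 * (6 + b)^2))
  }
  list(data = vol, affine = diag(c(spacing, spacing, spacing, 1)),
       spacing = spacing)
}
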