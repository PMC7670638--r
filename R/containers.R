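#' @useDynLib mreatlas, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Complex shear modulus field
#'
#' Voxelwise storage and loss moduli of a viscoelastic medium. Within the mask
#' the storage modulus must be positive and the loss modulus nonnegative;
#' outside the mask both volumes are zero by contract (NIfTI has no missing
#' value, so the mask travels with the data and all downstream statistics are
#' mask-aware).
#'
#' @param gp 3-D array of storage modulus G' in kPa.
#' @param gpp 3-D array of loss modulus G'' in kPa.
#' @param mask logical 3-D array, same shape.
#' @param spacing isotropic voxel size in mm.
#' @param affine 4x4 voxel-to-world matrix (RAS+, 0-based voxel indices).
#'   Defaults to a diagonal scaling by `spacing`.
#' @return An object of class `modulus_field`.
#' @export
modulus_field <- function(gp, gpp, mask, spacing, affine = NULL) {
  stopifnot(identical(dim(gp), dim(gpp)), identical(dim(gp), dim(mask)))
  mask <- array(as.logical(mask), dim(mask))
  gp <- gp * mask
  gpp <- gpp * mask
  if (any(gp[mask] <= 0)) stop("storage modulus must be > 0 inside the mask")
  if (any(gpp[mask] < 0)) stop("loss modulus must be >= 0 inside the mask")
  if (is.null(affine)) affine <- spacing_affine(spacing)
  structure(list(gp = gp, gpp = gpp, mask = mask, spacing = spacing,
                 affine = affine),
            class = "modulus_field")
}

#' @export
print.modulus_field <- function(x, ...) {
  cat("<modulus_field> ", paste(dim(x$mask), collapse = "x"),
      " @ ", x$spacing, " mm, ", sum(x$mask), " mask voxels\n", sep = "")
  cat(sprintf("  G' in [%.3f, %.3f] kPa; G'' in [%.3f, %.3f] kPa (mask)\n",
              min(x$gp[x$mask]), max(x$gp[x$mask]),
              min(x$gpp[x$mask]), max(x$gpp[x$mask])))
  invisible(x)
}

#' Steady-state displacement field
#'
#' Single-frequency complex displacement volume with three spatial components,
#' the measured-data analog of an MRE acquisition. Units are micrometres.
#'
#' @param u complex 4-D array with dim `c(nx, ny, nz, 3)`.
#' @param frequency actuation frequency in Hz.
#' @param spacing isotropic voxel size in mm.
#' @param mask logical 3-D array.
#' @param noise_sd per-component complex noise standard deviation in um
#'   (SD of the real part and of the imaginary part separately).
#' @param affine 4x4 voxel-to-world matrix.
#' @param solver optional list of solver diagnostics (residual etc.).
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(u, frequency, spacing, mask, noise_sd = 0,
                               affine = NULL, solver = NULL) {
  stopifnot(length(dim(u)) == 4L, dim(u)[4] == 3L,
            identical(dim(u)[1:3], dim(mask)))
  if (frequency <= 0) stop("frequency must be > 0")
  if (!all(is.finite(Re(u))) || !all(is.finite(Im(u))))
    stop("displacement field contains non-finite values")
  if (is.null(affine)) affine <- spacing_affine(spacing)
  structure(list(u = u, frequency = frequency, spacing = spacing,
                 mask = array(as.logical(mask), dim(mask)),
                 noise_sd = noise_sd, affine = affine, solver = solver),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat("<displacement_field> ", paste(dim(x$mask), collapse = "x"),
      " @ ", x$spacing, " mm, f = ", x$frequency, " Hz, noise_sd = ",
      signif(x$noise_sd, 4), " um\n", sep = "")
  invisible(x)
}

#' Derived property maps: shear stiffness and damping ratio
#'
#' @param mu 3-D array, shear stiffness in kPa.
#' @param xi 3-D array, damping ratio (dimensionless).
#' @param mask logical 3-D array.
#' @param spacing voxel size in mm.
#' @param affine 4x4 voxel-to-world matrix.
#' @param provenance named list (subject id, inversion settings hash, ...).
#' @return An object of class `property_maps`.
#' @export
property_maps <- function(mu, xi, mask, spacing, affine = NULL,
                          provenance = list()) {
  stopifnot(identical(dim(mu), dim(mask)), identical(dim(xi), dim(mask)))
  mask <- array(as.logical(mask), dim(mask))
  if (is.null(affine)) affine <- spacing_affine(spacing)
  structure(list(mu = mu * mask, xi = xi * mask, mask = mask,
                 spacing = spacing, affine = affine, provenance = provenance),
            class = "property_maps")
}

#' @export
print.property_maps <- function(x, ...) {
  cat("<property_maps> ", paste(dim(x$mask), collapse = "x"),
      " @ ", x$spacing, " mm\n", sep = "")
  cat(sprintf("  mask-mean mu = %.3f kPa, xi = %.4f\n",
              mean(x$mu[x$mask]), mean(x$xi[x$mask])))
  invisible(x)
}

spacing_affine <- function(spacing) {
  a <- diag(c(rep(spacing, 3), 1))
  a
}

#' Deterministic sub-seed for a named random substream
#'
#' All randomness in the package flows from a root seed through named
#' substreams so that stages can be re-run independently yet reproducibly.
#'
#' @param seed integer root seed.
#' @param name substream name (e.g. "cohort", "noise", "subzones").
#' @param k optional integer index (e.g. subject number).
#' @return An integer seed in `[0, 2^31)`.
#' @export
substream_seed <- function(seed, name, k = 0L) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  val <- (as.double(seed) * 48271 + h * 69621 + as.double(k) * 16807)
  as.integer(val %% 2147483647)
}
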