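# Reporting parameterization of the complex shear modulus.

#' Shear stiffness from storage and loss moduli
#'
#' mu = 2 |G*|^2 / (G' + |G*|) with G* = G' + i G''. Equal to rho c^2 for the
#' viscoelastic shear-wave speed c, so waves travel faster where mu is
#' larger; reduces to G' in the elastic limit G'' = 0.
#'
#' @param gp storage modulus G' (kPa), array or vector; must be > 0 where
#'   evaluated.
#' @param gpp loss modulus G'' (kPa), >= 0.
#' @return Shear stiffness in kPa, same shape as the inputs.
#' @export
compute_mu <- function(gp, gpp) {
  if (any(gp <= 0)) stop("G' must be > 0")
  gmag <- sqrt(gp^2 + gpp^2)
  2 * gmag^2 / (gp + gmag)
}

#' Damping ratio from storage and loss moduli
#'
#' xi = G'' / (2 G'): the relative attenuation level of shear oscillations;
#' larger values mean more fluid-like behaviour.
#'
#' @inheritParams compute_mu
#' @return Damping ratio (dimensionless), same shape as the inputs.
#' @export
compute_xi <- function(gp, gpp) {
  if (any(gp <= 0)) stop("G' must be > 0")
  gpp / (2 * gp)
}

#' Convert a complex modulus field to property maps
#'
#' Voxels inside the mask with nonpositive storage modulus are flagged,
#' excluded from the output mask, and counted in the provenance, rather than
#' silently propagated.
#'
#' @param modulus a [modulus_field()].
#' @param provenance named list carried into the result.
#' @return A [property_maps()] with mu (kPa) and xi volumes; masked-out
#'   voxels are stored as 0 with the mask carried alongside.
#' @export
modulus_to_property_maps <- function(modulus, provenance = list()) {
  mask <- modulus$mask
  bad <- mask & modulus$gp <= 0
  ok <- mask & !bad
  mu <- array(0, dim(mask))
  xi <- array(0, dim(mask))
  mu[ok] <- compute_mu(modulus$gp[ok], modulus$gpp[ok])
  xi[ok] <- compute_xi(modulus$gp[ok], modulus$gpp[ok])
  provenance$n_invalid_voxels <- sum(bad)
  property_maps(mu, xi, ok, modulus$spacing, modulus$affine, provenance)
}
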