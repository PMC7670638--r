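# Digital viscoelastic brain phantoms and synthetic cohorts.
#
# Geometry is parametric (ellipsoids, shells, shell sectors) so that every
# phantom is reproducible from code alone; an importer for real label maps in
# NIfTI is provided for users who have them. World coordinates are mm with
# voxel centre (i,j,k) at ((i,j,k)-1)*spacing.

#' Region specification for a phantom
#'
#' Holds the geometry and the ground-truth viscoelastic population parameters
#' of one labelled region: mean shear stiffness and damping ratio, their
#' between-subject standard deviations, and additive sex offsets (stiffness
#' offset added for males, damping-ratio offset added for females, matching
#' the direction of the sex contrasts this generator emulates).
#'
#' @param label integer label >= 1, unique within a phantom.
#' @param name region name.
#' @param geometry a list from [geom_ellipsoid()], [geom_shell()] or
#'   [geom_shell_sector()].
#' @param mu_mean,mu_sd shear stiffness mean and SD in kPa.
#' @param xi_mean,xi_sd damping ratio mean and SD (dimensionless).
#' @param sex_offset_mu stiffness offset in kPa added for male subjects.
#' @param sex_offset_xi damping-ratio offset added for female subjects.
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(label, name, geometry, mu_mean, xi_mean,
                        mu_sd = 0, xi_sd = 0,
                        sex_offset_mu = 0, sex_offset_xi = 0) {
  stopifnot(label >= 1, mu_mean > 0, xi_mean >= 0, xi_mean < 0.5,
            mu_sd >= 0, xi_sd >= 0)
  if (mu_mean - 3 * mu_sd <= 0)
    stop("region '", name, "': mu_mean - 3*mu_sd must stay positive")
  structure(list(label = as.integer(label), name = name, geometry = geometry,
                 mu_mean = mu_mean, xi_mean = xi_mean,
                 mu_sd = mu_sd, xi_sd = xi_sd,
                 sex_offset_mu = sex_offset_mu, sex_offset_xi = sex_offset_xi),
            class = "region_spec")
}

#' Geometric primitives for phantom regions
#'
#' `geom_ellipsoid` is an axis-aligned ellipsoid given by centre and semi-axes
#' in mm. `geom_shell` selects voxels whose normalized elliptical radius
#' relative to the brain ellipsoid lies in `[inner_frac, outer_frac]`.
#' `geom_shell_sector` additionally restricts to an azimuth range (degrees,
#' in the x-y plane about the brain centre), which is how a cortical shell is
#' partitioned into parcels.
#'
#' @param center,semiaxes numeric length-3, mm.
#' @param inner_frac,outer_frac radial fractions in (0, 1].
#' @param theta_min,theta_max azimuth range in degrees within (-180, 180].
#' @return A geometry description list.
#' @export
geom_ellipsoid <- function(center, semiaxes) {
  list(type = "ellipsoid", center = center, semiaxes = semiaxes)
}

#' @rdname geom_ellipsoid
#' @export
geom_shell <- function(inner_frac, outer_frac = 1) {
  stopifnot(inner_frac > 0, outer_frac <= 1, inner_frac < outer_frac)
  list(type = "shell", inner_frac = inner_frac, outer_frac = outer_frac)
}

#' @rdname geom_ellipsoid
#' @export
geom_shell_sector <- function(inner_frac, outer_frac, theta_min, theta_max) {
  list(type = "shell_sector", inner_frac = inner_frac,
       outer_frac = outer_frac, theta_min = theta_min, theta_max = theta_max)
}

#' Phantom specification
#'
#' @param shape integer length-3 grid shape in voxels.
#' @param spacing isotropic voxel size in mm (1.6 or 2.0 for the emulated
#'   acquisitions; any positive value is accepted).
#' @param brain brain-mask ellipsoid, a [geom_ellipsoid()].
#' @param background the background (white-matter) [region_spec()].
#' @param regions ordered list of [region_spec()]; later regions overwrite
#'   earlier ones deterministically.
#' @param rho tissue density in kg/m^3. Not a quantity with an established
#'   in vivo consensus for this pipeline; the standard soft-tissue value of
#'   1000 is the default.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape, spacing, brain, background, regions = list(),
                         rho = 1000) {
  labs <- vapply(c(list(background), regions), `[[`, integer(1), "label")
  if (anyDuplicated(labs)) stop("region labels must be unique")
  structure(list(shape = as.integer(shape), spacing = spacing, brain = brain,
                 background = background, regions = regions, rho = rho),
            class = "phantom_spec")
}

voxel_coords <- function(shape, spacing) {
  list(x = (seq_len(shape[1]) - 1) * spacing,
       y = (seq_len(shape[2]) - 1) * spacing,
       z = (seq_len(shape[3]) - 1) * spacing)
}

ellipsoid_inside <- function(co, center, semiaxes, shape) {
  dx2 <- ((co$x - center[1]) / semiaxes[1])^2
  dy2 <- ((co$y - center[2]) / semiaxes[2])^2
  dz2 <- ((co$z - center[3]) / semiaxes[3])^2
  r2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  array(r2 <= 1, shape)
}

geom_voxels <- function(geom, spec, co) {
  shape <- spec$shape
  if (geom$type == "ellipsoid")
    return(ellipsoid_inside(co, geom$center, geom$semiaxes, shape))
  ctr <- spec$brain$center
  ax <- spec$brain$semiaxes
  dx2 <- ((co$x - ctr[1]) / ax[1])^2
  dy2 <- ((co$y - ctr[2]) / ax[2])^2
  dz2 <- ((co$z - ctr[3]) / ax[3])^2
  r <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
  sel <- r >= geom$inner_frac & r <= geom$outer_frac
  if (geom$type == "shell_sector") {
    th <- outer(atan2(rep(1, shape[1]) %o% (co$y - ctr[2]), (co$x - ctr[1]) %o%
                      rep(1, shape[2])) * 180 / pi, rep(1, shape[3]))
    dim(th) <- shape
    th[th == 180] <- -180  # half-open convention so sectors tile the circle
    sel <- sel & th >= geom$theta_min & th < geom$theta_max
  }
  array(sel, shape)
}

#' Build the label volume and brain mask of a phantom
#'
#' Fills the brain mask with the background label, then paints each region in
#' order; later regions overwrite earlier ones. A region whose geometry
#' extends outside the brain mask is an error (shells and sectors are inside
#' by construction).
#'
#' @param spec a [phantom_spec()].
#' @return A list with `labels` (integer array, 0 outside brain), `mask`
#'   (logical array), `spacing`, `affine`, and the `spec` itself.
#' @export
build_phantom <- function(spec) {
  if (!is.null(spec$prebuilt_labels))
    return(list(labels = spec$prebuilt_labels,
                mask = spec$prebuilt_labels > 0, spacing = spec$spacing,
                affine = spacing_affine(spec$spacing), spec = spec))
  co <- voxel_coords(spec$shape, spec$spacing)
  mask <- ellipsoid_inside(co, spec$brain$center, spec$brain$semiaxes,
                           spec$shape)
  labels <- array(0L, spec$shape)
  labels[mask] <- spec$background$label
  for (rg in spec$regions) {
    vox <- geom_voxels(rg$geometry, spec, co)
    if (rg$geometry$type == "ellipsoid" && any(vox & !mask))
      stop("region '", rg$name, "' extends outside the brain mask")
    labels[vox & mask] <- rg$label
  }
  list(labels = labels, mask = mask, spacing = spec$spacing,
       affine = spacing_affine(spec$spacing), spec = spec)
}

#' Convert shear stiffness and damping ratio to storage and loss moduli
#'
#' Closed-form inverse of the reporting parameterization
#' mu = 2|G*|^2 / (G' + |G*|), xi = G'' / (2 G'): with a = sqrt(1 + 4 xi^2),
#' G' = mu (1 + a) / (2 a^2) and G'' = 2 xi G'. Applying the forward formulas
#' to the result reproduces (mu, xi) to machine precision.
#'
#' @param mu shear stiffness in kPa (> 0), vectorized.
#' @param xi damping ratio in [0, 0.5), vectorized.
#' @return A list with elements `gp` and `gpp` in kPa.
#' @export
mu_xi_to_modulus <- function(mu, xi) {
  if (any(mu <= 0)) stop("mu must be > 0")
  if (any(xi < 0 | xi >= 0.5)) stop("xi must lie in [0, 0.5)")
  a <- sqrt(1 + 4 * xi^2)
  gp <- mu * (1 + a) / (2 * a^2)
  list(gp = gp, gpp = 2 * xi * gp)
}

trunc_sample <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  truncnorm::rtruncnorm(n, a = lower, b = upper, mean = mean, sd = sd)
}

#' Sample a synthetic cohort from a phantom specification
#'
#' Per subject and per region, shear stiffness and damping ratio are drawn
#' from normal distributions truncated at 3 SD (and at physical bounds:
#' stiffness positive, damping ratio in [0, 0.5)), with the sex offsets of
#' each [region_spec()] and an optional additive study-level shift applied to
#' the mean. Variation is applied on the (mu, xi) scale, where population
#' dispersion is reported, and converted to (G', G'') per subject.
#'
#' @param spec a [phantom_spec()].
#' @param n_subjects number of subjects (>= 2 for a cohort; 1 is allowed for
#'   smoke runs).
#' @param sex_ratio fraction of female subjects (the emulated population is
#'   78 F of 134).
#' @param n_studies number of study sites; subjects are assigned round-robin.
#' @param seed root seed; every subject's draw is a deterministic function of
#'   it.
#' @param study_mu_sd,study_xi_sd SD of the per-study additive shifts
#'   (default 0: single-protocol cohort).
#' @param csv_path optional path; if given, the cohort table
#'   (subject,sex,study,seed) is written as CSV.
#' @return A list with `subjects` (data frame), `fields` (list of
#'   [modulus_field()]), `truth` (long data frame of sampled mu/xi per subject
#'   and region), and the built `phantom`.
#' @export
sample_cohort <- function(spec, n_subjects, sex_ratio = 78 / 134,
                          n_studies = 1, seed = 1,
                          study_mu_sd = 0, study_xi_sd = 0,
                          csv_path = NULL) {
  ph <- build_phantom(spec)
  regions <- c(list(spec$background), spec$regions)
  nf <- round(n_subjects * sex_ratio)
  sexes <- c(rep("F", nf), rep("M", n_subjects - nf))
  set.seed(substream_seed(seed, "cohort-sex"))
  sexes <- sample(sexes)
  studies <- LETTERS[(seq_len(n_subjects) - 1) %% n_studies + 1]
  set.seed(substream_seed(seed, "cohort-study-shift"))
  study_mu <- stats::rnorm(n_studies, 0, study_mu_sd)
  study_xi <- stats::rnorm(n_studies, 0, study_xi_sd)
  names(study_mu) <- names(study_xi) <- LETTERS[seq_len(n_studies)]
  subj_seed <- vapply(seq_len(n_subjects), function(k)
    substream_seed(seed, "cohort-subject", k), integer(1))
  fields <- vector("list", n_subjects)
  truth <- list()
  for (s in seq_len(n_subjects)) {
    set.seed(subj_seed[s])
    gp <- array(0, spec$shape)
    gpp <- array(0, spec$shape)
    for (rg in regions) {
      mu_m <- rg$mu_mean + if (sexes[s] == "M") rg$sex_offset_mu else 0
      xi_m <- rg$xi_mean + if (sexes[s] == "F") rg$sex_offset_xi else 0
      mu_m <- mu_m + study_mu[[studies[s]]]
      xi_m <- xi_m + study_xi[[studies[s]]]
      mu <- trunc_sample(1, mu_m, rg$mu_sd,
                         max(1e-6, mu_m - 3 * rg$mu_sd), mu_m + 3 * rg$mu_sd)
      xi <- trunc_sample(1, xi_m, rg$xi_sd,
                         max(0, xi_m - 3 * rg$xi_sd),
                         min(0.4999, xi_m + 3 * rg$xi_sd))
      if (mu <= 0) mu <- mu_m  # unreachable under the truncation bounds
      g <- mu_xi_to_modulus(mu, xi)
      sel <- ph$labels == rg$label
      gp[sel] <- g$gp
      gpp[sel] <- g$gpp
      truth[[length(truth) + 1]] <- data.frame(
        subject = s, region = rg$name, mu = mu, xi = xi)
    }
    fields[[s]] <- modulus_field(gp, gpp, ph$mask, spec$spacing, ph$affine)
  }
  subjects <- data.frame(subject = seq_len(n_subjects), sex = sexes,
                         study = studies, seed = subj_seed,
                         stringsAsFactors = FALSE)
  if (!is.null(csv_path))
    utils::write.csv(subjects, csv_path, row.names = FALSE)
  list(subjects = subjects, fields = fields,
       truth = do.call(rbind, truth), phantom = ph)
}

#' Reference viscoelastic population values
#'
#' Registry of the regional shear-stiffness and damping-ratio population
#' parameters (modified population marginal means and SDs, with sex-specific
#' columns) that the synthetic cohorts emulate, for the four region families:
#' global compartments, subcortical gray matter, white-matter tracts, and
#' cortical parcels. `basis = "text"` selects the post-outlier-removal global
#' summaries; `basis = "marginal"` (default) the tabulated marginal means.
#'
#' @param family one of "global", "sgm", "wmt", "cgm".
#' @param basis "marginal" or "text" (the latter only for "global").
#' @return A data frame with one row per region.
#' @export
mre_reference_values <- function(family = c("global", "sgm", "wmt", "cgm"),
                                 basis = c("marginal", "text")) {
  family <- match.arg(family)
  basis <- match.arg(basis)
  df <- function(...) data.frame(..., stringsAsFactors = FALSE)
  tab <- switch(family,
    global = df(
      region = c("Global", "WM", "SGM", "CGM"),
      mu_mean = c(2.62, 2.95, 3.46, 2.37),
      mu_sd = c(.21, .21, .38, .18),
      mu_male = c(2.64, 2.98, 3.48, 2.39),
      mu_female = c(2.60, 2.93, 3.45, 2.35),
      xi_mean = c(.205, .221, .200, .204),
      xi_sd = c(.024, .024, .027, .027),
      xi_male = c(.203, .217, .197, .203),
      xi_female = c(.207, .225, .203, .205)),
    sgm = df(
      region = c("AM", "CA", "HC", "PA", "PU", "TH"),
      mu_mean = c(3.04, 3.19, 2.82, 3.95, 3.91, 3.41),
      mu_sd = c(.69, .50, .56, .50, .44, .50),
      mu_male = c(3.17, 3.24, 2.74, 4.04, 3.98, 3.50),
      mu_female = c(2.90, 3.14, 2.89, 3.86, 3.83, 3.31),
      xi_mean = c(.158, .232, .179, .192, .195, .200),
      xi_sd = c(.041, .041, .041, .035, .035, .035),
      xi_male = c(.157, .229, .175, .188, .191, .200),
      xi_female = c(.160, .236, .183, .196, .198, .201)),
    wmt = df(
      region = c("CST", "ATR", "PTR", "CRa", "CC", "FMa", "FMi", "FX",
                 "UN", "IFOF", "ILF", "SLF"),
      mu_mean = c(3.30, 3.54, 3.56, 3.36, 3.05, 3.21, 3.21, 3.02,
                  3.36, 3.46, 3.29, 3.19),
      mu_sd = c(.39, .38, .34, .33, .32, .28, .27, .56, .35, .29, .34, .35),
      mu_male = c(3.39, 3.59, 3.55, 3.38, 3.01, 3.16, 3.23, 3.09,
                  3.38, 3.46, 3.30, 3.24),
      mu_female = c(3.21, 3.50, 3.57, 3.34, 3.09, 3.25, 3.18, 2.96,
                    3.35, 3.46, 3.27, 3.15),
      xi_mean = c(.214, .220, .223, .248, .208, .250, .218, .224,
                  .236, .226, .231, .243),
      xi_sd = c(.030, .027, .032, .030, .027, .032, .030, .056,
                .041, .027, .035, .032),
      xi_male = c(.208, .221, .219, .247, .208, .254, .221, .226,
                  .229, .224, .224, .239),
      xi_female = c(.221, .218, .228, .249, .207, .247, .215, .223,
                    .243, .228, .238, .246)),
    cgm = df(
      region = c("SFC", "RMF", "PRE", "LaO", "LiO", "CN", "SPC", "POST",
                 "PCN", "STC", "ITC", "FSG"),
      mu_mean = c(2.21, 2.16, 2.44, 1.99, 3.12, 2.42, 2.04, 2.40,
                  2.76, 2.58, 2.20, 2.58),
      mu_sd = c(.22, .21, .26, .18, .26, .25, .27, .27, .32, .26, .21, .24),
      mu_male = c(2.22, 2.19, 2.51, 1.98, 3.09, 2.41, 2.12, 2.50,
                  2.75, 2.62, 2.23, 2.58),
      mu_female = c(2.20, 2.14, 2.36, 1.99, 3.14, 2.43, 1.96, 2.31,
                    2.77, 2.54, 2.16, 2.58),
      xi_mean = c(.172, .242, .229, .196, .104, .147, .258, .242,
                  .127, .249, .213, .144),
      xi_sd = c(.027, .038, .041, .027, .021, .024, .038, .035,
                .021, .044, .044, .030),
      xi_male = c(.172, .243, .220, .198, .100, .143, .260, .235,
                  .129, .237, .209, .137),
      xi_female = c(.171, .240, .238, .193, .108, .151, .256, .249,
                    .125, .261, .218, .150)))
  if (basis == "text") {
    if (family != "global")
      stop("post-outlier text summaries are registered for 'global' only")
    tab$mu_sd <- c(.17, .18, .35, .16)
    tab$xi_mean <- c(.208, .225, .200, .206)
    tab$xi_sd <- c(.015, .015, .022, .019)
  }
  tab
}
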