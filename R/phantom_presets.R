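# Standard phantom families used throughout the tests and the recovery
# studies. Geometry sizes respect the resolution limits of 50 Hz shear waves
# at 1.6-2 mm voxels: every structure is at least 4 voxels across its minor
# axis, and thin-sheet regions (cortical shell, tracts) are >= 8 mm thick.

std_brain_geom <- function(shape, spacing) {
  extent <- (shape - 1) * spacing
  geom_ellipsoid(center = extent / 2,
                 semiaxes = c(0.42, 0.45, 0.42) * shape * spacing)
}

region_from_stats <- function(label, name, geometry, stats, sd_scale = 1,
                              sex_effects = FALSE) {
  row <- stats[stats$region == name, ]
  if (nrow(row) != 1) stop("unknown region: ", name)
  if (sex_effects) {
    region_spec(label, name, geometry,
                mu_mean = row$mu_female, xi_mean = row$xi_male,
                mu_sd = row$mu_sd * sd_scale, xi_sd = row$xi_sd * sd_scale,
                sex_offset_mu = row$mu_male - row$mu_female,
                sex_offset_xi = row$xi_female - row$xi_male)
  } else {
    region_spec(label, name, geometry,
                mu_mean = row$mu_mean, xi_mean = row$xi_mean,
                mu_sd = row$mu_sd * sd_scale, xi_sd = row$xi_sd * sd_scale)
  }
}

#' Standard phantom families
#'
#' Constructors for the phantom geometries used by the recovery studies:
#' a homogeneous whole-brain phantom, a two-compartment phantom (white-matter
#' core plus cortical shell), a three-compartment phantom (adding deep
#' subcortical ellipsoids), a six-region subcortical phantom (amygdala,
#' caudate, hippocampus, pallidum, putamen, thalamus analogs), a multi-tract
#' white-matter phantom with a soft fornix analog, and a cortical-parcel
#' phantom whose shell is split into four azimuthal parcels. Ground-truth
#' population parameters default to the reference registry
#' ([mre_reference_values()]).
#'
#' @param shape grid shape (isotropic default 32^3).
#' @param spacing voxel size in mm.
#' @param sd_scale multiplier on the registry between-subject SDs (0 gives a
#'   deterministic cohort).
#' @param sex_effects if TRUE, regional sex offsets are taken from the
#'   registry's male/female columns.
#' @param basis registry basis for the global family ("text" = post-outlier
#'   summaries, used by default for global compartments).
#' @return A [phantom_spec()].
#' @name phantom_presets
NULL

#' @rdname phantom_presets
#' @param region which global-compartment row parameterizes the homogeneous
#'   phantom ("Global", "WM", "SGM", or "CGM").
#' @export
phantom_homogeneous <- function(shape = c(32, 32, 32), spacing = 2,
                                sd_scale = 1, basis = "text",
                                region = "Global", sex_effects = FALSE) {
  g <- mre_reference_values("global", basis)
  if (sex_effects)
    g[, c("mu_male", "mu_female", "xi_male", "xi_female")] <-
      mre_reference_values("global", "marginal")[
        , c("mu_male", "mu_female", "xi_male", "xi_female")]
  brain <- std_brain_geom(shape, spacing)
  bg <- region_from_stats(1L, region, brain, g, sd_scale, sex_effects)
  phantom_spec(shape, spacing, brain, bg)
}

two_compartment_regions <- function(shape, spacing, sd_scale, basis,
                                    sex_effects) {
  g <- mre_reference_values("global", basis)
  if (sex_effects) # sex columns live on the marginal basis
    g[, c("mu_male", "mu_female", "xi_male", "xi_female")] <-
      mre_reference_values("global", "marginal")[
        , c("mu_male", "mu_female", "xi_male", "xi_female")]
  brain <- std_brain_geom(shape, spacing)
  bg <- region_from_stats(1L, "WM", brain, g, sd_scale, sex_effects)
  shell <- region_from_stats(2L, "CGM", geom_shell(0.72, 1), g, sd_scale,
                             sex_effects)
  list(brain = brain, bg = bg, shell = shell, g = g)
}

#' @rdname phantom_presets
#' @export
phantom_two_compartment <- function(shape = c(32, 32, 32), spacing = 2,
                                    sd_scale = 1, sex_effects = FALSE,
                                    basis = "text") {
  p <- two_compartment_regions(shape, spacing, sd_scale, basis, sex_effects)
  phantom_spec(shape, spacing, p$brain, p$bg, list(p$shell))
}

#' @rdname phantom_presets
#' @export
phantom_three_compartment <- function(shape = c(32, 32, 32), spacing = 2,
                                      sd_scale = 1, sex_effects = FALSE,
                                      basis = "text") {
  p <- two_compartment_regions(shape, spacing, sd_scale, basis, sex_effects)
  ctr <- p$brain$center
  sgm <- lapply(1:2, function(k) {
    off <- c(-1, 1)[k] * 11
    rg <- region_from_stats(2L + k, "SGM",
                            geom_ellipsoid(ctr + c(off, 0, 0), c(8, 11, 8)),
                            p$g, sd_scale, sex_effects)
    rg$name <- c("SGM_L", "SGM_R")[k]
    rg
  })
  phantom_spec(shape, spacing, p$brain, p$bg, c(list(p$shell), sgm))
}

#' @rdname phantom_presets
#' @export
phantom_sgm6 <- function(shape = c(32, 32, 32), spacing = 2, sd_scale = 1,
                         sex_effects = FALSE) {
  s <- mre_reference_values("sgm")
  gtab <- mre_reference_values("global", "text")
  brain <- std_brain_geom(shape, spacing)
  bg <- region_from_stats(1L, "WM", brain, gtab, sd_scale)
  ctr <- brain$center
  pos <- rbind(c(13, 0, 0), c(-13, 0, 0), c(0, 14, 0),
               c(0, -14, 0), c(0, 0, 13), c(0, 0, -13))
  regions <- lapply(seq_len(6), function(k)
    region_from_stats(1L + k, s$region[k],
                      geom_ellipsoid(ctr + pos[k, ], c(8.5, 9.5, 8.5)),
                      s, sd_scale, sex_effects))
  phantom_spec(shape, spacing, brain, bg, regions)
}

#' @rdname phantom_presets
#' @export
phantom_wmt <- function(shape = c(32, 32, 32), spacing = 2, sd_scale = 1) {
  w <- mre_reference_values("wmt")
  gtab <- mre_reference_values("global", "text")
  brain <- std_brain_geom(shape, spacing)
  bg <- region_from_stats(1L, "WM", brain, gtab, sd_scale)
  ctr <- brain$center
  regions <- list(
    region_from_stats(2L, "FX",
                      geom_ellipsoid(ctr, c(5, 16, 5)), w, sd_scale),
    region_from_stats(3L, "PTR",
                      geom_ellipsoid(ctr + c(14, 0, 0), c(6, 13, 6)),
                      w, sd_scale),
    region_from_stats(4L, "CRa",
                      geom_ellipsoid(ctr + c(-14, 0, 0), c(6, 13, 6)),
                      w, sd_scale))
  phantom_spec(shape, spacing, brain, bg, regions)
}

#' @rdname phantom_presets
#' @export
phantom_cortical <- function(shape = c(32, 32, 32), spacing = 2,
                             sd_scale = 1) {
  cg <- mre_reference_values("cgm")
  gtab <- mre_reference_values("global", "text")
  brain <- std_brain_geom(shape, spacing)
  bg <- region_from_stats(1L, "WM", brain, gtab, sd_scale)
  parcels <- c("LiO", "LaO", "PCN", "SFC")
  th <- cbind(c(-180, -90, 0, 90), c(-90, 0, 90, 180))
  regions <- lapply(seq_along(parcels), function(k)
    region_from_stats(1L + k, parcels[k],
                      geom_shell_sector(0.72, 1, th[k, 1], th[k, 2]),
                      cg, sd_scale))
  phantom_spec(shape, spacing, brain, bg, regions)
}

#' Import a phantom from an existing label map
#'
#' For users with real (e.g. atlas-derived) segmentations: builds a phantom
#' whose geometry is the imported integer label volume instead of parametric
#' primitives.
#'
#' @param labels integer 3-D array (0 = outside brain).
#' @param spacing voxel size in mm.
#' @param region_table data frame with columns label, name, mu_mean, xi_mean
#'   and optionally mu_sd, xi_sd, sex_offset_mu, sex_offset_xi.
#' @param rho density in kg/m^3.
#' @return A list like [build_phantom()]'s result (the phantom is prebuilt).
#' @export
phantom_from_labels <- function(labels, spacing, region_table, rho = 1000) {
  stopifnot(all(c("label", "name", "mu_mean", "xi_mean") %in%
                names(region_table)))
  getcol <- function(cn, default) {
    if (cn %in% names(region_table)) region_table[[cn]] else
      rep(default, nrow(region_table))
  }
  regions <- lapply(seq_len(nrow(region_table)), function(i)
    region_spec(region_table$label[i], region_table$name[i],
                geometry = list(type = "imported"),
                mu_mean = region_table$mu_mean[i],
                xi_mean = region_table$xi_mean[i],
                mu_sd = getcol("mu_sd", 0)[i],
                xi_sd = getcol("xi_sd", 0)[i],
                sex_offset_mu = getcol("sex_offset_mu", 0)[i],
                sex_offset_xi = getcol("sex_offset_xi", 0)[i]))
  spec <- structure(list(shape = dim(labels), spacing = spacing,
                         brain = NULL, background = regions[[1]],
                         regions = regions[-1], rho = rho,
                         prebuilt_labels = labels),
                    class = "phantom_spec")
  list(labels = labels, mask = labels > 0, spacing = spacing,
       affine = spacing_affine(spacing), spec = spec)
}
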