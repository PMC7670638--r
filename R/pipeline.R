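# End-to-end pipeline driver: simulate -> qc -> invert -> maps ->
# normalize -> atlas -> stats, with a content-hashed artifact manifest.

PHANTOM_BUILDERS <- list(
  homogeneous = function(args) do.call(phantom_homogeneous, args),
  two_compartment = function(args) do.call(phantom_two_compartment, args),
  three_compartment = function(args) do.call(phantom_three_compartment, args),
  sgm6 = function(args) do.call(phantom_sgm6, args),
  wmt = function(args) do.call(phantom_wmt, args),
  cortical = function(args) do.call(phantom_cortical, args))

#' Pipeline configuration
#'
#' @param outdir output directory (created if needed).
#' @param seed root seed; all stage randomness derives from it via named
#'   substreams (cohort, noise, subzone order, QC Monte Carlo).
#' @param phantom phantom family name (one of `names(PHANTOM_BUILDERS)`)
#' @param phantom_args list of arguments for the phantom constructor.
#' @param n_subjects cohort size.
#' @param sex_ratio,n_studies cohort composition.
#' @param snr_target calibrated OSS-SNR of the added noise (NULL or 0 for
#'   noiseless).
#' @param qc_threshold OSS-SNR gate threshold.
#' @param inversion list of [inversion_config()] overrides.
#' @param rho,frequency physics parameters.
#' @param template_space if TRUE, property maps are resampled to the
#'   91 x 109 x 91 / 2 mm template grid before atlas averaging.
#' @param run_stats fit the mixed models on the extracted region means
#'   (needs >= 2 regions and enough subjects per region).
#' @param erode_rois if TRUE, label-derived ROI masks are eroded by one
#'   voxel before extraction.
#' @param write_subject_volumes write per-subject NIfTI volumes (slower).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1, phantom = "two_compartment",
                            phantom_args = list(), n_subjects = 4,
                            sex_ratio = 78 / 134, n_studies = 1,
                            snr_target = 5, qc_threshold = 3,
                            inversion = list(), rho = 1000, frequency = 50,
                            template_space = FALSE, erode_rois = TRUE,
                            run_stats = TRUE,
                            write_subject_volumes = FALSE) {
  stopifnot(phantom %in% names(PHANTOM_BUILDERS))
  structure(list(outdir = outdir, seed = seed, phantom = phantom,
                 phantom_args = phantom_args, n_subjects = n_subjects,
                 sex_ratio = sex_ratio, n_studies = n_studies,
                 snr_target = snr_target, qc_threshold = qc_threshold,
                 inversion = inversion, rho = rho, frequency = frequency,
                 template_space = template_space, erode_rois = erode_rois,
                 run_stats = run_stats,
                 write_subject_volumes = write_subject_volumes),
            class = "pipeline_config")
}

#' Read/write a pipeline configuration as YAML
#'
#' @param path YAML file.
#' @param config a [pipeline_config()].
#' @return `read_pipeline_config` returns a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Stages, in order: cohort simulation (ground-truth moduli), wave
#' simulation with noise calibrated to the target OSS-SNR, the quality gate
#' (failing subjects are excluded from all downstream stages and listed in
#' the manifest), subzone nonlinear inversion, property-map computation,
#' optional normalization to the template grid, atlas averaging, ROI mean
#' extraction, and mixed-model statistics (when at least two regions exist).
#' Every written artifact is recorded in a JSON manifest with its MD5
#' content hash.
#'
#' @param config a [pipeline_config()].
#' @param progress print stage progress.
#' @return A list with `manifest`, `cohort`, `qc`, `inversions`, `maps`,
#'   `atlas`, `roi_table`, `stats`, `excluded_subjects`, `status`.
#' @export
run_pipeline <- function(config, progress = FALSE) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (progress) message(sprintf(...))
  artifacts <- character(0)
  put <- function(path) artifacts <<- c(artifacts, path)

  say("stage: simulate cohort (%d subjects, phantom '%s')",
      config$n_subjects, config$phantom)
  spec <- PHANTOM_BUILDERS[[config$phantom]](config$phantom_args)
  cohort_csv <- file.path(config$outdir, "cohort.csv")
  cohort <- sample_cohort(spec, config$n_subjects, config$sex_ratio,
                          config$n_studies,
                          seed = substream_seed(config$seed, "cohort"),
                          csv_path = cohort_csv)
  put(cohort_csv)
  icfg <- do.call(inversion_config, config$inversion)

  qc_reports <- list()
  inversions <- list()
  maps <- list()
  passed <- logical(config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    say("subject %d: forward simulation", s)
    field <- simulate_waves(cohort$fields[[s]], rho = config$rho,
                            frequency = config$frequency)
    sigma <- 0
    if (!is.null(config$snr_target) && config$snr_target > 0)
      sigma <- calibrate_noise_sd(field, config$snr_target)
    noisy <- add_noise(field, sigma,
                       seed = substream_seed(config$seed, "noise", s))
    qc <- oss_snr(noisy, threshold = config$qc_threshold)
    qc_reports[[s]] <- qc
    passed[s] <- qc$pass
    if (!qc$pass) {
      say("subject %d failed QC (OSS-SNR %.2f)", s, qc$oss_snr)
      next
    }
    say("subject %d: subzone inversion", s)
    inv <- subzone_nli(noisy, icfg, rho = config$rho,
                       seed = substream_seed(config$seed, "subzones", s),
                       qc = qc)
    inversions[[s]] <- inv
    pm <- modulus_to_property_maps(inv$modulus,
                                   provenance = list(subject = s))
    if (config$template_space)
      pm <- resample_to_template(pm, diag(4), template_grid())
    maps[[s]] <- pm
    if (config$write_subject_volumes) {
      pr <- file.path(config$outdir, sprintf("sub-%03d", s))
      write_nifti(pm$mu, paste0(pr, "_mu.nii"), pm$spacing, pm$affine)
      write_nifti(pm$xi, paste0(pr, "_dr.nii"), pm$spacing, pm$affine)
      put(paste0(pr, "_mu.nii")); put(paste0(pr, "_dr.nii"))
    }
  }
  qc_json <- file.path(config$outdir, "qc.json")
  jsonlite::write_json(lapply(qc_reports, function(q)
    list(oss_snr = q$oss_snr, pass = q$pass)), qc_json, auto_unbox = TRUE,
    digits = 10)
  put(qc_json)

  included <- which(passed)
  status <- "ok"
  atlas <- NULL
  roi_table <- NULL
  stats_out <- NULL
  if (!length(included)) {
    status <- "no-subjects-passed-qc"
  } else {
    say("stage: atlas (%d subjects)", length(included))
    atlas <- build_atlas(maps[included])
    for (nm in c("mu_mean", "xi_mean", "mu_sd", "xi_sd")) {
      p <- file.path(config$outdir, paste0("atlas_", nm, ".nii"))
      write_nifti(atlas[[nm]], p, atlas$spacing, atlas$affine)
      put(p)
    }
    cov_p <- file.path(config$outdir, "coverage.nii")
    write_nifti(atlas$coverage, cov_p, atlas$spacing, atlas$affine,
                datatype = "int16")
    put(cov_p)

    say("stage: ROI statistics")
    ph <- cohort$phantom
    labels <- ph$labels
    if (config$template_space) {
      # carry each region mask to the template grid through the same
      # (identity) transform used for the maps
      rois <- make_roi_masks(labels, "label",
                             names = region_names(spec))
      rois <- lapply(rois, function(m) {
        r <- resample_array(m * 1, ph$affine, diag(4), template_grid())
        r$data >= 0.5 & r$inside
      })
    } else {
      rois <- if (config$erode_rois)
        make_roi_masks(labels, "label", names = region_names(spec))
      else {
        labs <- sort(setdiff(unique(as.vector(labels)), 0))
        stats::setNames(lapply(labs, function(l) labels == l),
                        region_names(spec))
      }
    }
    rows <- list()
    for (s in included) {
      rm <- extract_roi_means(maps[[s]], rois)
      rm$subject <- s
      rm$sex <- cohort$subjects$sex[s]
      rm$study <- cohort$subjects$study[s]
      rows[[length(rows) + 1]] <- rm
    }
    roi_table <- do.call(rbind, rows)
    roi_csv <- file.path(config$outdir, "roi_table.csv")
    utils::write.csv(roi_table[, c("subject", "sex", "study", "region",
                                   "measure", "value")],
                     roi_csv, row.names = FALSE)
    put(roi_csv)
    if (config$run_stats && length(rois) >= 2 &&
        length(included) >= 2 * length(rois)) {
      stats_out <- list(mu = analyze_rois(roi_table, "mu"),
                        xi = analyze_rois(roi_table, "xi"))
      stats_json <- file.path(config$outdir, "stats.json")
      jsonlite::write_json(lapply(stats_out, function(a) list(
        tests = a$fit$tests,
        marginal_means = a$fit$marginal_means,
        n_removed = if (is.null(a$removed)) 0 else nrow(a$removed))),
        stats_json, auto_unbox = TRUE, digits = 10, force = TRUE)
      put(stats_json)
    }
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("mreatlas")),
    seed = config$seed,
    config_hash = digest_obj(unclass(config)),
    status = status,
    excluded_subjects = which(!passed),
    artifacts = lapply(artifacts, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))))
  man_path <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE)
  list(manifest = manifest, cohort = cohort, qc = qc_reports,
       inversions = inversions, maps = maps, atlas = atlas,
       roi_table = roi_table, stats = stats_out,
       excluded_subjects = which(!passed), status = status)
}

region_names <- function(spec) {
  regs <- c(list(spec$background), spec$regions)
  ord <- order(vapply(regs, `[[`, integer(1), "label"))
  vapply(regs[ord], `[[`, character(1), "name")
}

digest_obj <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf)
  unname(tools::md5sum(tf))
}
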