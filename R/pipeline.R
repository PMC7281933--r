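#' End-to-end pipeline
#'
#' Orchestrates simulate -> preprocess -> fit -> compare -> associate on a
#' synthetic cohort, writing every artifact (NIfTI volumes, TSV tables, JSON
#' manifest) into a run directory. Re-running with an identical
#' configuration reproduces identical artifacts; the manifest records the
#' package version, a config hash, all seeds and per-file checksums.
#'
#' @name pipeline
NULL

# Tidy data.frame of clusters from per-parameter analysis results.
cluster_table <- function(analyses, alpha = 0.05) {
  rows <- list()
  for (par in names(analyses)) for (contrast in names(analyses[[par]])) {
    for (cl in analyses[[par]][[contrast]]$clusters) {
      peak <- if (!is.null(cl$peak_mm)) cl$peak_mm else cl$peak_vox
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = par, contrast = contrast,
        peak_x_mm = peak[1], peak_y_mm = peak[2], peak_z_mm = peak[3],
        threshold = cl$forming_threshold, size_voxels = cl$size_voxels,
        peak_t = cl$peak_t, p_fwe = cl$p_fwe,
        significant = cl$p_fwe < alpha, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(parameter = character(), contrast = character(),
                      peak_x_mm = numeric(), peak_y_mm = numeric(),
                      peak_z_mm = numeric(), threshold = numeric(),
                      size_voxels = integer(), peak_t = numeric(),
                      p_fwe = numeric(), significant = logical()))
  do.call(rbind, rows)
}

# Union mask of the significant clusters of one parameter (both contrasts).
significant_union_mask <- function(param_analyses, alpha, dim3) {
  out <- array(FALSE, dim = dim3)
  for (contrast in names(param_analyses))
    for (cl in param_analyses[[contrast]]$clusters)
      if (cl$p_fwe < alpha) out <- out | cluster_mask(cl)
  out
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' @param config Run configuration from [load_run_config()] (or a named list
#'   of overrides applied to the defaults).
#' @param out_dir Output directory; created, and must be empty (runs are
#'   write-once).
#' @param write_dwi Write the raw per-subject DWI series (large); the
#'   derived maps and tables are always written.
#' @return Invisible list: `spec`, `cohort`, `maps` (per subject),
#'   `analyses`, `clusters` (data.frame), `intersection` (mask),
#'   `associations` (data.frame or NULL), `manifest` (path).
#' @export
run_pipeline <- function(config = list(), out_dir, write_dwi = FALSE) {
  cfg <- load_run_config(NULL, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (length(list.files(out_dir)))
    stop("output directory is not empty; runs are write-once")

  spec <- do.call(phantom_spec,
                  utils::modifyList(list(seed = cfg$seed), cfg$phantom))
  affine <- phantom_affine(spec$grid_shape, spec$voxel_size_mm)

  ## simulate ----------------------------------------------------------------
  cohort_data <- generate_cohort(spec)
  write_bvals(spec$b_schedule, file.path(out_dir, "bvals.txt"))
  write_cohort(cohort_data$cohort, file.path(out_dir, "cohort.tsv"))
  write_nifti_vol(cohort_data$effect_region,
                  file.path(out_dir, "effect_region.nii.gz"),
                  spec$voxel_size_mm, affine)
  if (write_dwi) {
    dir.create(file.path(out_dir, "dwi"))
    for (id in names(cohort_data$dwi)) {
      avg <- average_directions(cohort_data$dwi[[id]])
      write_nifti_vol(avg$signal, file.path(out_dir, "dwi",
                                            paste0(id, "_dwi.nii.gz")),
                      spec$voxel_size_mm, affine)
    }
  }

  ## preprocess + fit --------------------------------------------------------
  fit_opt <- ivim_fit_options(b_cut = cfg$b_cut, fast_rate = cfg$fast_rate)
  dir.create(file.path(out_dir, "maps"))
  maps <- list()
  for (id in names(cohort_data$dwi)) {
    pre <- preprocess_dwi(cohort_data$dwi[[id]], cfg$smooth_fwhm_mm,
                          cfg$smooth_target)
    fit <- fit_ivim_volume(pre, cfg$fit_method, fit_opt)
    if (cfg$smooth_target == "maps" && cfg$smooth_fwhm_mm > 0)
      for (par in c("v_bw", "D", "D_star", "flow"))
        fit[[par]] <- gaussian_smooth(fit[[par]], cfg$smooth_fwhm_mm,
                                      spec$voxel_size_mm)
    maps[[id]] <- fit
    for (par in c("v_bw", "D", "D_star", "flow"))
      write_nifti_vol(fit[[par]],
                      file.path(out_dir, "maps",
                                sprintf("%s_%s.nii.gz", id, par)),
                      spec$voxel_size_mm, affine)
  }

  ## compare -----------------------------------------------------------------
  pat <- cohort_data$cohort$subject_id[cohort_data$cohort$group == "patient"]
  ctl <- cohort_data$cohort$subject_id[cohort_data$cohort$group == "control"]
  analyses <- list()
  for (par in cfg$parameters) {
    maps_pat <- lapply(maps[pat], `[[`, par)
    maps_ctl <- lapply(maps[ctl], `[[`, par)
    analyses[[par]] <- list(
      "patient>control" = group_cluster_analysis(
        maps_pat, maps_ctl, cfg$forming_threshold, "positive",
        cfg$connectivity, cfg$correction, cfg$n_perm,
        derive_seed(cfg$seed, 500L), affine),
      "patient<control" = group_cluster_analysis(
        maps_pat, maps_ctl, cfg$forming_threshold, "negative",
        cfg$connectivity, cfg$correction, cfg$n_perm,
        derive_seed(cfg$seed, 501L), affine))
  }
  clusters <- cluster_table(analyses, cfg$alpha)
  write.table(clusters, file.path(out_dir, "clusters.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (par in cfg$parameters) {
    tm <- analyses[[par]][[1]]$tmap
    write_nifti_vol(tm$t, file.path(out_dir, sprintf("tmap_%s.nii.gz", par)),
                    spec$voxel_size_mm, affine)
  }
  sig_masks <- lapply(cfg$parameters, function(par)
    significant_union_mask(analyses[[par]], cfg$alpha, spec$grid_shape))
  names(sig_masks) <- cfg$parameters
  intersection <- intersect_significant_clusters(sig_masks)
  write_nifti_vol(intersection, file.path(out_dir, "intersection.nii.gz"),
                  spec$voxel_size_mm, affine)

  ## associate ---------------------------------------------------------------
  associations <- NULL
  if (sum(intersection) > 0 && "associate" %in% cfg$stages) {
    associations <- run_association_battery(
      maps, intersection, cohort_data$cohort, cfg$parameters,
      cfg$covariates, group = cfg$association_group)
    write.table(associations, file.path(out_dir, "associations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## manifest ----------------------------------------------------------------
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("ivimtools")),
    config = cfg,
    config_hash = config_hash(cfg),
    seed = cfg$seed,
    n_significant_clusters = sum(clusters$significant),
    intersection_voxels = sum(intersection),
    artifacts = as.list(stats::setNames(unname(tools::md5sum(files)),
                                        basename(files))))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(spec = spec, cohort = cohort_data$cohort,
                 truth = cohort_data$truth, maps = maps, analyses = analyses,
                 clusters = clusters, intersection = intersection,
                 associations = associations, manifest = manifest_path))
}
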