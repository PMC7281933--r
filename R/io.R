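#' Shared readers and writers
#'
#' NIfTI-1 volumes, plain-text b-value files (one value per line, s/mm^2),
#' tab-separated cohort tables, and the YAML run configuration.
#'
#' @name formats
NULL

#' Affine of a phantom grid
#'
#' Diagonal affine with the voxel size on the diagonal and the origin at the
#' grid centre. Synthetic grids carry no standard-space meaning; mm
#' coordinates exist only to report cluster peaks on a physical scale.
#'
#' @param grid_shape Integer length-3 grid shape.
#' @param voxel_size_mm Voxel dimensions, mm.
#' @return 4x4 affine matrix (voxel, 0-based -> mm).
#' @export
phantom_affine <- function(grid_shape, voxel_size_mm) {
  aff <- diag(c(voxel_size_mm, 1))
  aff[1:3, 4] <- -voxel_size_mm * (grid_shape - 1) / 2
  aff
}

#' Write a volume as NIfTI-1
#'
#' @param x 3D or 4D numeric array (logical masks are stored as 0/1).
#' @param file Output path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm Voxel dimensions, mm.
#' @param affine Optional 4x4 affine stored as the sform/qform.
#' @return The file path, invisibly.
#' @export
write_nifti_vol <- function(x, file, voxel_size_mm = c(1, 1, 1),
                            affine = NULL) {
  if (is.logical(x)) x <- array(as.numeric(x), dim = dim(x))
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- voxel_size_mm
  if (!is.null(affine)) {
    img <- RNifti::asNifti(x, reference = list(
      pixdim = c(-1, voxel_size_mm, rep(1, 4))))
    RNifti::sform(img) <- structure(affine, code = 2L)
    RNifti::qform(img) <- structure(affine, code = 2L)
  }
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' Read a NIfTI-1 volume as a plain array
#'
#' @param file Path to a `.nii`/`.nii.gz` file.
#' @return Numeric array with attributes `voxel_size_mm` and `affine`.
#' @export
read_nifti_vol <- function(file) {
  img <- RNifti::readNifti(file)
  arr <- array(as.numeric(img), dim = dim(img))
  attr(arr, "voxel_size_mm") <- RNifti::pixdim(img)[seq_len(min(3, length(dim(img))))]
  attr(arr, "affine") <- structure(RNifti::xform(img), code = NULL)
  arr
}

#' Write / read a b-value text file
#'
#' One b value per line, s/mm^2, matching the order of the volumes on the b
#' axis.
#'
#' @param b_values Numeric vector.
#' @param file Path.
#' @return `write_bvals`: the path, invisibly. `read_bvals`: numeric vector.
#' @export
write_bvals <- function(b_values, file) {
  writeLines(format(b_values, scientific = FALSE, trim = TRUE), file)
  invisible(file)
}

#' @rdname write_bvals
#' @export
read_bvals <- function(file) {
  b <- suppressWarnings(as.numeric(readLines(file)))
  if (anyNA(b)) stop("non-numeric entry in b-value file ", file)
  if (b[1] != 0 || any(b < 0) || any(diff(b) <= 0))
    stop("b values must start at 0 and be strictly increasing: ", file)
  b
}

#' Write / read a cohort table
#'
#' Tab-separated with at least `subject_id` and `group` columns; remaining
#' columns are covariates.
#'
#' @param cohort data.frame.
#' @param file Path.
#' @return `write_cohort`: the path, invisibly. `read_cohort`: data.frame.
#' @export
write_cohort <- function(cohort, file) {
  stopifnot(all(c("subject_id", "group") %in% names(cohort)))
  write.table(cohort, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(file) {
  tab <- read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(c("subject_id", "group"), names(tab))
  if (length(missing))
    stop("cohort table ", file, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(tab$subject_id))
    stop("duplicate subject_id in cohort table ", file)
  tab
}

# Recognized run-configuration keys with defaults; validation rejects
# unknown keys before any computation.
default_run_config <- function() {
  list(
    stages = c("simulate", "preprocess", "fit", "compare", "associate"),
    seed = 1L,
    phantom = list(),                 # overrides passed to phantom_spec()
    smooth_fwhm_mm = 8,
    smooth_target = "series",
    fit_method = "segmented",
    b_cut = 200,
    fast_rate = "sum",
    forming_threshold = 2.0,
    connectivity = 18L,
    correction = "rft",
    n_perm = 999L,
    alpha = 0.05,
    association_group = "patient",
    covariates = c("vca_z", "pms_z", "sledai", "null_z"),
    parameters = c("v_bw", "D", "D_star", "flow")
  )
}

#' Load and validate a run configuration
#'
#' YAML file of `key: value` pairs; unknown keys are rejected, missing keys
#' take documented defaults (see the run-configuration section of the
#' package vignette).
#'
#' @param file Path to a YAML config, or NULL for pure defaults.
#' @param overrides Named list applied on top of the file.
#' @return Validated config list.
#' @export
load_run_config <- function(file = NULL, overrides = list()) {
  cfg <- default_run_config()
  user <- if (is.null(file)) list() else yaml::read_yaml(file)
  user <- utils::modifyList(user, overrides)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(cfg, user)
  stopifnot(cfg$fit_method %in% c("segmented", "full_nls"),
            cfg$correction %in% c("rft", "perm"),
            cfg$smooth_target %in% c("series", "maps"),
            cfg$connectivity %in% c(6, 18, 26))
  cfg
}

# Stable hash of a config (md5 of its deparsed canonical form).
config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(cfg[order(names(cfg))]), tmp)
  unname(tools::md5sum(tmp))
}
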