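#' Synthetic two-group IVIM phantom
#'
#' The phantom emulates the study design the pipeline targets: two cohorts of
#' subjects scanned with a multi-b diffusion schedule, a posterior effect
#' region in which the patient group has lower blood-water fraction and
#' higher parenchymal diffusion, pseudo-diffusion and flow product, Rician
#' magnitude noise, spatially smooth true parameter fields, and clinical
#' covariates linearly coupled to regional parameter values. Ground truth is
#' returned alongside the data so every downstream stage can be tested for
#' recovery.
#'
#' @name phantom
NULL

# Default 15-point b schedule, s/mm^2.
default_b_schedule <- function() {
  c(0, 5, 10, 20, 30, 40, 60, 80, 120, 160, 200, 300, 500, 750, 1000)
}

# Ellipsoid mask centred in the posterior third of the grid (y axis taken as
# anterior-posterior); mimics a midline posterior cluster without anatomy.
default_effect_region <- function(grid_shape) {
  centre <- c(grid_shape[1] / 2 + 0.5,
              grid_shape[2] * 5 / 6,
              grid_shape[3] / 2 + 0.5)
  radii <- pmax(c(grid_shape[1] / 3.4, grid_shape[2] / 5.3, grid_shape[3] / 2.8), 1.5)
  ix <- seq_len(grid_shape[1]); iy <- seq_len(grid_shape[2]); iz <- seq_len(grid_shape[3])
  dx2 <- ((ix - centre[1]) / radii[1])^2
  dy2 <- ((iy - centre[2]) / radii[2])^2
  dz2 <- ((iz - centre[3]) / radii[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
}

#' Construct and validate a phantom specification
#'
#' Defaults describe the emulated study: an 11-per-group cohort on a
#' 24 x 24 x 12 grid of 3.75 x 3.75 x 5 mm voxels, the 15-value b schedule,
#' three orthogonal gradient directions, and literature-typical healthy brain
#' IVIM values (v_bw 0.05, D 0.8e-3 mm^2/s, D* 10e-3 mm^2/s). Patient-group
#' shifts inside the effect region lower v_bw and raise D, D* and the flow
#' product. Rician noise scale is relative to S0.
#'
#' @param grid_shape Integer length-3 voxel grid.
#' @param voxel_size_mm Voxel dimensions, mm.
#' @param b_schedule Strictly increasing b values starting at 0, s/mm^2.
#' @param n_per_group Subjects per group (>= 2).
#' @param n_directions Gradient directions per b value.
#' @param s0 Baseline (b = 0) signal in arbitrary scanner units.
#' @param baseline_params Named list `v_bw`, `D`, `D_star` for healthy tissue.
#' @param effect_deltas Additive shifts applied to the patient group inside
#'   the effect region.
#' @param effect_region Logical 3D mask; default posterior ellipsoid.
#' @param between_subject_sd Per-parameter SD of the subject-level offset.
#' @param field_sd Per-parameter SD of the smooth spatial field.
#' @param field_smooth_fwhm_mm Smoothness (FWHM, mm) of the true fields.
#' @param noise_sigma Rician scale as a fraction of S0.
#' @param noise_model `"rician"` (magnitude MRI) or `"gaussian"` (oracle
#'   tests).
#' @param covariate_model Named list of covariates; each entry is a list with
#'   `parameter` (one of v_bw, D, D_star, flow), `slope`, `intercept`,
#'   `noise_sd`. Covariate = intercept + slope * true regional mean + noise.
#' @param seed Base seed for all randomness in the cohort.
#' @return A validated `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(24L, 24L, 12L),
                         voxel_size_mm = c(3.75, 3.75, 5),
                         b_schedule = default_b_schedule(),
                         n_per_group = 11L,
                         n_directions = 3L,
                         s0 = 600,
                         baseline_params = list(v_bw = 0.05, D = 0.8e-3,
                                                D_star = 10e-3),
                         effect_deltas = list(v_bw = -0.015, D = 0.35e-3,
                                              D_star = 14e-3),
                         effect_region = NULL,
                         between_subject_sd = list(v_bw = 0.003, D = 0.03e-3,
                                                   D_star = 1.0e-3),
                         field_sd = list(v_bw = 0.003, D = 0.04e-3,
                                         D_star = 0.8e-3),
                         field_smooth_fwhm_mm = 12,
                         noise_sigma = 0.02,
                         noise_model = c("rician", "gaussian"),
                         covariate_model = default_covariate_model(),
                         seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (is.null(effect_region)) effect_region <- default_effect_region(grid_shape)
  spec <- structure(list(
    grid_shape = as.integer(grid_shape), voxel_size_mm = voxel_size_mm,
    b_schedule = b_schedule, n_per_group = as.integer(n_per_group),
    n_directions = as.integer(n_directions), s0 = s0,
    baseline_params = baseline_params, effect_deltas = effect_deltas,
    effect_region = effect_region, between_subject_sd = between_subject_sd,
    field_sd = field_sd, field_smooth_fwhm_mm = field_smooth_fwhm_mm,
    noise_sigma = noise_sigma, noise_model = noise_model,
    covariate_model = covariate_model, seed = as.integer(seed)),
    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

# Default covariate coupling: a visuoconstructional-like Z score and a
# psychomotor-like Z score inversely coupled to regional flow, a
# disease-activity-like score inversely coupled to regional v_bw, and a null
# covariate with zero slope.
default_covariate_model <- function() {
  list(
    vca_z  = list(parameter = "flow",  slope = -3000, intercept = 2.4,
                  noise_sd = 0.10),
    pms_z  = list(parameter = "flow",  slope = -3000, intercept = 2.5,
                  noise_sd = 0.15),
    sledai = list(parameter = "v_bw",  slope = -300,  intercept = 17.7,
                  noise_sd = 1.5),
    null_z = list(parameter = "flow",  slope = 0,     intercept = 0,
                  noise_sd = 1)
  )
}

validate_phantom_spec <- function(spec) {
  b <- spec$b_schedule
  if (length(b) < 4 || b[1] != 0 || any(b < 0) || any(diff(b) <= 0))
    stop("b_schedule must start at 0, be non-negative and strictly increasing")
  if (spec$n_per_group < 2) stop("n_per_group must be >= 2")
  if (spec$n_directions < 1) stop("n_directions must be >= 1")
  if (spec$noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (!identical(dim(spec$effect_region), as.integer(spec$grid_shape)) &&
      !identical(dim(spec$effect_region), spec$grid_shape))
    stop("effect_region mask does not match grid_shape")
  check_param_set <- function(p, label) {
    if (p$v_bw < 0 || p$v_bw > 1)
      stop(sprintf("%s: v_bw = %g outside [0, 1]", label, p$v_bw))
    if (p$D < 0) stop(sprintf("%s: D = %g negative", label, p$D))
    if (p$D_star < p$D)
      stop(sprintf("%s: D_star = %g below D = %g", label, p$D_star, p$D))
  }
  base <- spec$baseline_params
  check_param_set(base, "baseline_params")
  shifted <- list(v_bw = base$v_bw + spec$effect_deltas$v_bw,
                  D = base$D + spec$effect_deltas$D,
                  D_star = base$D_star + spec$effect_deltas$D_star)
  check_param_set(shifted, "baseline_params + effect_deltas")
  for (nm in names(spec$covariate_model)) {
    cm <- spec$covariate_model[[nm]]
    if (!cm$parameter %in% c("v_bw", "D", "D_star", "flow"))
      stop(sprintf("covariate '%s' references unknown parameter '%s'",
                   nm, cm$parameter))
    if (cm$noise_sd < 0) stop(sprintf("covariate '%s': negative noise_sd", nm))
  }
  invisible(spec)
}

#' Generate a subject's true IVIM parameter fields
#'
#' Each parameter field is the group-level regional mean (baseline, plus the
#' effect shift inside the effect region for patients) plus a subject-level
#' random offset plus a smooth Gaussian random field, clamped to the physical
#' bounds 0 <= v_bw <= 1, D >= 0, D* >= D. Deterministic for a fixed
#' `subject_seed`.
#'
#' @param spec A `phantom_spec`.
#' @param group `"control"` or `"patient"`.
#' @param subject_seed Integer seed for this subject's fields.
#' @return A `ground_truth` list of 3D arrays `v_bw`, `D`, `D_star`, `flow`
#'   plus the effect-region mask.
#' @export
build_true_fields <- function(spec, group = c("control", "patient"),
                              subject_seed = 1L) {
  group <- match.arg(group)
  validate_phantom_spec(spec)
  gs <- spec$grid_shape
  fwhm_vox <- spec$field_smooth_fwhm_mm / spec$voxel_size_mm
  fields <- with_seed(subject_seed, {
    out <- list()
    for (par in c("v_bw", "D", "D_star")) {
      mean_map <- array(spec$baseline_params[[par]], dim = gs)
      if (group == "patient")
        mean_map[spec$effect_region] <-
          mean_map[spec$effect_region] + spec$effect_deltas[[par]]
      offset <- rnorm(1, 0, spec$between_subject_sd[[par]])
      grf <- smooth_noise_field(gs, fwhm_vox) * spec$field_sd[[par]]
      out[[par]] <- mean_map + offset + grf
    }
    out
  })
  fields$v_bw <- pmin(pmax(fields$v_bw, 0), 1)
  fields$D <- pmax(fields$D, 0)
  fields$D_star <- pmax(fields$D_star, fields$D)
  fields$flow <- fields$v_bw * fields$D_star
  structure(list(fields = fields, effect_region = spec$effect_region,
                 group = group, subject_seed = subject_seed),
            class = "ground_truth")
}

# Rician magnitude: modulus of (signal + g1, g2) with iid N(0, sigma) parts.
rician_noise <- function(signal, sigma) {
  if (sigma == 0) return(signal)
  sqrt((signal + rnorm(length(signal), 0, sigma))^2 +
         rnorm(length(signal), 0, sigma)^2)
}

#' Simulate a DWI acquisition from true parameter fields
#'
#' The noiseless signal per voxel and b value follows the bi-exponential
#' model `S0 * [(1 - v_bw) exp(-b D) + v_bw exp(-b (D + D*))]`; one noise
#' realization is drawn per gradient direction. Rician noise is the magnitude
#' of the noiseless signal perturbed by two independent zero-mean Gaussians
#' of SD `noise_sigma * S0` (Gaussian additive noise available for oracle
#' tests).
#'
#' @param truth A `ground_truth` from [build_true_fields()].
#' @param spec The `phantom_spec` (supplies schedule, S0, noise model).
#' @param n_directions Number of gradient directions (default from spec).
#' @param seed Integer seed for the noise.
#' @return A `dwi_series` with 5D signal (x, y, z, b, direction).
#' @export
simulate_dwi <- function(truth, spec, n_directions = spec$n_directions,
                         seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  if (n_directions < 1) stop("n_directions must be >= 1")
  gs <- spec$grid_shape
  b <- spec$b_schedule
  f <- truth$fields
  nb <- length(b)
  # noiseless fractional signal, voxels x b
  frac <- ivim_signal(as.vector(f$v_bw), as.vector(f$D), as.vector(f$D_star),
                      rep(b, each = prod(gs)))
  noiseless <- spec$s0 * array(frac, dim = c(gs, nb))
  sigma <- spec$noise_sigma * spec$s0
  sig <- with_seed(seed, {
    out <- array(0, dim = c(gs, nb, n_directions))
    for (dir in seq_len(n_directions)) {
      out[, , , , dir] <- if (spec$noise_model == "rician")
        rician_noise(noiseless, sigma)
      else
        noiseless + rnorm(length(noiseless), 0, sigma)
    }
    out
  })
  dwi_series(sig, b_schedule = b, voxel_size_mm = spec$voxel_size_mm,
             brain_mask = array(TRUE, dim = gs))
}

#' Container for a diffusion-weighted series
#'
#' @param signal 4D (x, y, z, b) or 5D (x, y, z, b, direction) array of
#'   non-negative magnitudes.
#' @param b_schedule b values, s/mm^2; length must match the b axis.
#' @param voxel_size_mm Voxel dimensions, mm.
#' @param brain_mask Logical 3D array; default all TRUE.
#' @return A `dwi_series` object.
#' @export
dwi_series <- function(signal, b_schedule, voxel_size_mm,
                       brain_mask = NULL) {
  d <- dim(signal)
  if (!length(d) %in% c(4, 5)) stop("signal must be 4D or 5D")
  if (d[4] != length(b_schedule))
    stop("b axis length does not match b_schedule")
  if (any(signal < 0)) stop("magnitude signal must be non-negative")
  if (is.null(brain_mask)) brain_mask <- array(TRUE, dim = d[1:3])
  stopifnot(identical(dim(brain_mask), d[1:3]))
  structure(list(signal = signal, b_schedule = b_schedule,
                 voxel_size_mm = voxel_size_mm, brain_mask = brain_mask,
                 normalized = FALSE),
            class = "dwi_series")
}

#' Generate a full two-group phantom cohort
#'
#' Builds per-subject ground-truth fields and DWI series for both groups and
#' a cohort table whose covariates are linear in the true regional mean of a
#' named parameter: covariate = intercept + slope * regional mean + Gaussian
#' noise. All seeds are derived from `spec$seed`, so identical specs give
#' byte-identical cohorts.
#'
#' @param spec A `phantom_spec`.
#' @param simulate Simulate the DWI acquisitions (default). With
#'   `simulate = FALSE` only ground-truth fields and covariates are
#'   generated — the fast path for design and power studies; the covariates
#'   and truth are identical to the full run.
#' @return List with `dwi` (named list of `dwi_series`; empty when
#'   `simulate = FALSE`), `cohort` (data.frame: subject_id, group, one
#'   column per covariate), `truth` (named list of `ground_truth`), and
#'   `effect_region`.
#' @export
generate_cohort <- function(spec, simulate = TRUE) {
  validate_phantom_spec(spec)
  groups <- rep(c("control", "patient"), each = spec$n_per_group)
  ids <- sprintf("%s_%02d", ifelse(groups == "control", "ctl", "pat"),
                 c(seq_len(spec$n_per_group), seq_len(spec$n_per_group)))
  truth <- list(); dwi <- list()
  regmean <- matrix(NA_real_, nrow = length(ids), ncol = 4,
                    dimnames = list(ids, c("v_bw", "D", "D_star", "flow")))
  for (i in seq_along(ids)) {
    tr <- build_true_fields(spec, groups[i],
                            subject_seed = derive_seed(spec$seed, 2L * i))
    truth[[ids[i]]] <- tr
    if (simulate)
      dwi[[ids[i]]] <- simulate_dwi(tr, spec,
                                    seed = derive_seed(spec$seed, 2L * i + 1L))
    for (par in colnames(regmean))
      regmean[i, par] <- mean(tr$fields[[par]][spec$effect_region])
  }
  cohort <- data.frame(subject_id = ids, group = groups,
                       stringsAsFactors = FALSE)
  for (nm in names(spec$covariate_model)) {
    cm <- spec$covariate_model[[nm]]
    noise <- with_seed(derive_seed(spec$seed, 9000L + match(nm, names(spec$covariate_model))),
                       rnorm(length(ids), 0, cm$noise_sd))
    cohort[[nm]] <- cm$intercept + cm$slope * regmean[, cm$parameter] + noise
  }
  list(dwi = dwi, cohort = cohort, truth = truth,
       effect_region = spec$effect_region)
}
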