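#' Preprocessing of multi-direction, multi-b diffusion series
#'
#' Raw acquisitions hold one magnitude volume per b value and gradient
#' direction. The fitter consumes a single fractional-signal series per voxel,
#' so preprocessing (1) averages the gradient directions per b value,
#' (2) smooths each b-value volume with a Gaussian kernel specified in mm and
#' (3) divides every voxel's series by its b = 0 value.
#'
#' @name preprocess
NULL

# One-axis Gaussian convolution matrix with nearest-neighbour replication at
# the boundary: out-of-range taps fold their weight onto the edge voxel, so
# every row sums to 1 (constants preserved) and interior columns sum to 1
# (mass conserved away from the boundary).
gauss_kernel_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  w <- dnorm(-r:r, sd = sigma_vox)
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- pmin(pmax(i + (-r:r), 1L), n)
    for (k in seq_along(j)) K[i, j[k]] <- K[i, j[k]] + w[k]
  }
  K
}

# Separable 3D convolution of array `x` with per-axis kernel matrices.
apply_separable <- function(x, K1, K2, K3) {
  d <- dim(x)
  # axis 1
  x <- array(K1 %*% matrix(x, nrow = d[1]), dim = d)
  # axis 2
  x <- aperm(x, c(2, 1, 3))
  x <- array(K2 %*% matrix(x, nrow = d[2]), dim = d[c(2, 1, 3)])
  x <- aperm(x, c(2, 1, 3))
  # axis 3
  x <- aperm(x, c(3, 1, 2))
  x <- array(K3 %*% matrix(x, nrow = d[3]), dim = d[c(3, 1, 2)])
  aperm(x, c(2, 3, 1))
}

#' Gaussian smoothing of a 3D map or 4D series
#'
#' Separable Gaussian convolution. The kernel width is given as full width at
#' half maximum in mm and converted per axis to voxel units, so anisotropic
#' voxels receive anisotropic (in voxels) kernels of isotropic physical width.
#' Boundaries use nearest-neighbour replication. `fwhm_mm = 0` is the
#' identity.
#'
#' @param x 3D array, or 4D array smoothed volume-by-volume along axis 4.
#' @param fwhm_mm Kernel full width at half maximum, mm (scalar, >= 0).
#' @param voxel_size_mm Numeric length-3 voxel dimensions in mm.
#' @return Array of the same shape as `x`.
#' @export
gaussian_smooth <- function(x, fwhm_mm, voxel_size_mm) {
  if (length(fwhm_mm) != 1 || !is.finite(fwhm_mm) || fwhm_mm < 0)
    stop("fwhm_mm must be a single non-negative number")
  if (fwhm_mm == 0) return(x)
  stopifnot(length(voxel_size_mm) == 3, all(voxel_size_mm > 0))
  d <- dim(x)
  sig <- fwhm_to_sigma(fwhm_mm) / voxel_size_mm
  Ks <- lapply(1:3, function(a) gauss_kernel_matrix(d[a], sig[a]))
  if (length(d) == 3)
    return(apply_separable(x, Ks[[1]], Ks[[2]], Ks[[3]]))
  if (length(d) == 4) {
    out <- x
    for (v in seq_len(d[4]))
      out[, , , v] <- apply_separable(x[, , , v], Ks[[1]], Ks[[2]], Ks[[3]])
    return(out)
  }
  stop("x must be a 3D or 4D array")
}

#' Smooth unit-variance Gaussian noise field
#'
#' White Gaussian noise convolved with a Gaussian kernel of the requested
#' per-axis FWHM (in voxels), then rescaled by the exact per-voxel standard
#' deviation implied by the kernel weights so the output has unit variance
#' everywhere, including near the boundary. This is the spatial process the
#' phantom uses for its true parameter fields and the null simulations use
#' for calibration: smoothness is what cluster-level random field inference
#' assumes.
#'
#' @param dim Integer length-3 grid shape.
#' @param fwhm_vox Per-axis kernel FWHM in voxel units (length 1 or 3).
#' @return 3D array, marginally standard normal with Gaussian autocorrelation.
#' @export
smooth_noise_field <- function(dim, fwhm_vox) {
  stopifnot(length(dim) == 3)
  fwhm_vox <- rep_len(fwhm_vox, 3)
  sig <- fwhm_to_sigma(fwhm_vox)
  Ks <- lapply(1:3, function(a) gauss_kernel_matrix(dim[a], sig[a]))
  z <- array(rnorm(prod(dim)), dim = dim)
  z <- apply_separable(z, Ks[[1]], Ks[[2]], Ks[[3]])
  # variance of the smoothed field factorises over axes: rowSums of squared
  # kernel weights
  v1 <- rowSums(Ks[[1]]^2); v2 <- rowSums(Ks[[2]]^2); v3 <- rowSums(Ks[[3]]^2)
  sd_map <- sqrt(outer(outer(v1, v2), v3))
  z / sd_map
}

#' Average the gradient-direction axis of a DWI series
#'
#' Diffusion gradients applied along orthogonal directions yield one volume
#' per direction and b value; the isotropic signal used for model fitting is
#' their arithmetic mean per b value.
#'
#' @param dwi A `dwi_series` whose signal has a direction axis (5D).
#' @return The same `dwi_series` with the direction axis averaged out (4D).
#' @export
average_directions <- function(dwi) {
  stopifnot(inherits(dwi, "dwi_series"))
  d <- dim(dwi$signal)
  if (length(d) != 5)
    stop("dwi has no direction axis to average")
  if (d[5] < 1) stop("empty direction axis")
  sig <- array(rowMeans(matrix(dwi$signal, ncol = d[5])), dim = d[1:4])
  dwi$signal <- sig
  dwi
}

#' Normalize a DWI series to its b = 0 volume
#'
#' Divides every voxel's signal series by that voxel's b = 0 value, producing
#' the fractional signal the bi-exponential model describes. Voxels whose
#' b = 0 signal is not strictly positive cannot be normalized; they are
#' removed from the brain mask (with a count recorded in
#' `attr(, "n_invalid_b0")`) rather than aborting the run.
#'
#' @param dwi A 4D `dwi_series` whose first b value is 0.
#' @return `dwi_series` of fractional signal; b = 0 entry is exactly 1 inside
#'   the (possibly reduced) mask.
#' @export
normalize_to_b0 <- function(dwi) {
  stopifnot(inherits(dwi, "dwi_series"))
  if (dwi$b_schedule[1] != 0) stop("first b value must be 0")
  d <- dim(dwi$signal)
  if (length(d) == 5) stop("average directions before normalizing")
  sig <- dwi$signal
  b0 <- array(sig[, , , 1], dim = d[1:3])
  bad <- dwi$brain_mask & !(b0 > 0)
  mask <- dwi$brain_mask & (b0 > 0)
  b0safe <- ifelse(b0 > 0, b0, 1)
  out <- sweep(sig, 1:3, b0safe, "/")
  out[, , , 1] <- 1
  dwi$signal <- out
  dwi$brain_mask <- mask
  dwi$normalized <- TRUE
  attr(dwi, "n_invalid_b0") <- sum(bad)
  dwi
}

#' Standard preprocessing chain
#'
#' Fixed order: average gradient directions, smooth each b-value volume,
#' normalize to b = 0. An alternative order that skips series smoothing (for
#' smoothing the fitted maps instead) is selected with
#' `smooth_target = "maps"`; in that case the caller smooths the parameter
#' maps after fitting.
#'
#' @param dwi Raw `dwi_series` (4D or 5D).
#' @param fwhm_mm Smoothing kernel FWHM in mm (default 8).
#' @param smooth_target `"series"` (default) smooths the DWI volumes before
#'   fitting; `"maps"` leaves the series unsmoothed.
#' @return Normalized `dwi_series` ready for fitting.
#' @export
preprocess_dwi <- function(dwi, fwhm_mm = 8, smooth_target = c("series", "maps")) {
  smooth_target <- match.arg(smooth_target)
  if (length(dim(dwi$signal)) == 5) dwi <- average_directions(dwi)
  if (smooth_target == "series" && fwhm_mm > 0)
    dwi$signal <- gaussian_smooth(dwi$signal, fwhm_mm, dwi$voxel_size_mm)
  normalize_to_b0(dwi)
}
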