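#' @useDynLib ivimtools, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm dnorm pnorm qnorm pt median cor var cov
#' @importFrom utils read.delim write.table combn
NULL

# FWHM of a Gaussian kernel <-> its standard deviation.
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))
sigma_to_fwhm <- function(sigma) sigma * (2 * sqrt(2 * log(2)))

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so seeded helpers do not disturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a stream-specific seed from a base seed; stays inside 32-bit range.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(stream) * 10007) %%
               2147483629) + 1L
}

# Dice overlap of two logical masks.
#' Dice overlap coefficient between two masks
#'
#' @param a,b Logical arrays of identical shape.
#' @return 2|A&B| / (|A| + |B|); NaN when both masks are empty.
#' @export
dice_overlap <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}

# Flat (column-major) index -> 0-based voxel coordinates.
index_to_vox <- function(idx, dim) {
  idx0 <- idx - 1L
  cbind(idx0 %% dim[1],
        (idx0 %/% dim[1]) %% dim[2],
        idx0 %/% (dim[1] * dim[2]))
}

# 0-based voxel coordinates -> mm via a 4x4 affine.
vox_to_mm <- function(vox, affine) {
  vox <- matrix(vox, ncol = 3)
  t(affine %*% rbind(t(vox), 1))[, 1:3, drop = FALSE]
}
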