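#' Cluster-level group inference on parameter maps
#'
#' Voxel-wise two-sample t tests between cohorts, supra-threshold cluster
#' formation at a nominal T-score threshold, and cluster-level
#' family-wise-error-corrected p values, either analytically from
#' Gaussian random field theory (with smoothness estimated from standardized
#' residuals) or non-parametrically from the permutation distribution of the
#' maximum cluster extent.
#'
#' @name group_inference
NULL

# Stack per-subject 3D maps into an n x V matrix over a common finite mask.
stack_maps <- function(maps, mask = NULL) {
  d <- dim(maps[[1]])
  for (m in maps) stopifnot(identical(dim(m), d))
  finite <- Reduce("&", lapply(maps, function(m) is.finite(m)))
  if (!is.null(mask)) finite <- finite & mask
  mv <- which(finite)
  Y <- do.call(rbind, lapply(maps, function(m) m[mv]))
  list(Y = Y, mask = finite, mv = mv, dim = d)
}

# Pooled two-sample t for every column of an n x V matrix; rows idx_A are
# group A. Returns t and the pooled variance (for zero-variance removal).
pooled_t_matrix <- function(Y, idx_A) {
  n <- nrow(Y)
  nA <- length(idx_A); nB <- n - nA
  A <- Y[idx_A, , drop = FALSE]
  B <- Y[-idx_A, , drop = FALSE]
  mA <- colMeans(A); mB <- colMeans(B)
  ssA <- colSums(A^2) - nA * mA^2
  ssB <- colSums(B^2) - nB * mB^2
  sp2 <- (ssA + ssB) / (nA + nB - 2)
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  list(t = (mA - mB) / se, sp2 = sp2, df = nA + nB - 2)
}

#' Voxel-wise independent-sample t test between two groups of maps
#'
#' Pooled-variance two-sample t statistic per voxel, df = n_A + n_B - 2.
#' Positive t means group A exceeds group B. Voxels with zero pooled
#' variance (no information) are removed from the analysis mask.
#'
#' @param maps_A,maps_B Lists of per-subject 3D parameter maps (NA marks
#'   voxels outside each subject's validity mask).
#' @param mask Optional additional analysis mask.
#' @return A `tmap`: 3D `t` array (NA outside mask), `df`, `mask`,
#'   `n_A`, `n_B`.
#' @export
voxelwise_ttest <- function(maps_A, maps_B, mask = NULL) {
  if (length(maps_A) < 2 || length(maps_B) < 2)
    stop("need at least 2 subjects per group")
  st <- stack_maps(c(maps_A, maps_B), mask)
  res <- pooled_t_matrix(st$Y, seq_along(maps_A))
  keep <- res$sp2 > 0
  tarr <- array(NA_real_, dim = st$dim)
  tarr[st$mv[keep]] <- res$t[keep]
  m <- array(FALSE, dim = st$dim)
  m[st$mv[keep]] <- TRUE
  structure(list(t = tarr, df = res$df, mask = m,
                 n_A = length(maps_A), n_B = length(maps_B)),
            class = "tmap")
}

#' Standardized residuals of the two-group model
#'
#' Per-subject residuals about the group means, normalized voxel-wise to
#' unit sum of squares. These are the fields whose spatial derivatives feed
#' the smoothness estimator.
#'
#' @inheritParams voxelwise_ttest
#' @return List of per-subject 3D residual maps plus the common mask.
#' @export
group_residuals <- function(maps_A, maps_B, mask = NULL) {
  st <- stack_maps(c(maps_A, maps_B), mask)
  nA <- length(maps_A)
  idx_A <- seq_len(nA)
  mA <- colMeans(st$Y[idx_A, , drop = FALSE])
  mB <- colMeans(st$Y[-idx_A, , drop = FALSE])
  E <- st$Y - rbind(matrix(mA, nA, ncol(st$Y), byrow = TRUE),
                    matrix(mB, nrow(st$Y) - nA, ncol(st$Y), byrow = TRUE))
  norm <- sqrt(colSums(E^2))
  ok <- norm > 0
  res <- lapply(seq_len(nrow(E)), function(i) {
    m <- array(NA_real_, dim = st$dim)
    m[st$mv[ok]] <- E[i, ok] / norm[ok]
    m
  })
  msk <- array(FALSE, dim = st$dim)
  msk[st$mv[ok]] <- TRUE
  list(residuals = res, mask = msk)
}

#' Estimate field smoothness from residual maps
#'
#' Per-axis FWHM (in voxels) from the variance of spatial first differences
#' of the standardized residual fields: for a unit-variance Gaussian field
#' with Gaussian autocorrelation, Var(dX/dx) = 4 log(2) / FWHM^2, so
#' FWHM = sqrt(4 log 2 / lambda) with lambda the per-axis derivative
#' variance pooled over subjects and voxels. The search volume in resels is
#' the mask volume divided by the product of the per-axis FWHMs.
#'
#' @param residuals List (>= 3) of standardized residual 3D maps, e.g. from
#'   [group_residuals()].
#' @param mask Logical analysis mask.
#' @return A `smoothness` object: `fwhm_voxels` (length 3), `resel_count`.
#' @export
estimate_smoothness <- function(residuals, mask) {
  if (length(residuals) < 3) stop("need at least 3 residual maps")
  d <- dim(residuals[[1]])
  lambda <- numeric(3)
  count <- numeric(3)
  shift <- function(arr, axis) {
    idx <- lapply(d, seq_len)
    idx[[axis]] <- c(2:d[axis], d[axis])
    do.call("[", c(list(arr), idx))
  }
  for (axis in 1:3) {
    pair_ok <- mask & shift(mask, axis)
    # drop the wrapped last slice along this axis
    idx <- lapply(d, seq_len)
    idx[[axis]] <- seq_len(d[axis] - 1)
    keep <- array(FALSE, dim = d)
    keep <- do.call("[<-", c(list(keep), idx, list(TRUE)))
    pair_ok <- pair_ok & keep
    if (!any(pair_ok)) stop("mask too thin along axis ", axis)
    acc <- 0
    for (r in residuals) {
      dr <- shift(r, axis) - r
      acc <- acc + sum(dr[pair_ok]^2)
    }
    lambda[axis] <- acc / sum(pair_ok)
    count[axis] <- sum(pair_ok)
  }
  if (any(lambda <= 0))
    stop("flat residuals: smoothness undefined")
  # E[(X(i+1)-X(i))^2] = 2(1 - rho(1)) underestimates the derivative variance
  # on a lattice when the FWHM is only a few voxels; invert the Gaussian
  # autocorrelation model rho(h) = exp(-h^2 lambda / 2) exactly instead:
  # lambda = -2 log(1 - E/2).
  rho1 <- pmin(pmax(1 - lambda / 2, 1e-6), 1 - 1e-6)
  lambda <- -2 * log(rho1)
  fwhm <- sqrt(4 * log(2) / lambda)
  structure(list(fwhm_voxels = fwhm,
                 resel_count = sum(mask) / prod(fwhm)),
            class = "smoothness")
}

#' Form supra-threshold clusters of a t map
#'
#' Connected components of the supra-threshold set under 6-, 18- or
#' 26-neighbour connectivity (18 is the default, matching common
#' neuroimaging practice). For `direction = "negative"` the set is
#' `{t <= -threshold}`. Clusters are returned sorted by size (descending,
#' ties by first voxel in raster order), so labeling is deterministic.
#'
#' @param tmap A `tmap` from [voxelwise_ttest()].
#' @param forming_threshold Cluster-forming T-score threshold.
#' @param connectivity 6, 18 or 26.
#' @param direction `"positive"` (A > B) or `"negative"` (B > A).
#' @return List of `cluster_result` objects: flat `indices`, `size_voxels`,
#'   `peak_vox` (0-based voxel coordinates), `peak_t`, `forming_threshold`,
#'   `direction`, `connectivity`, `dim`.
#' @export
form_clusters <- function(tmap, forming_threshold, connectivity = 18,
                          direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  stopifnot(is.finite(forming_threshold))
  tv <- tmap$t
  supra <- is.finite(tv) &
    (if (direction == "positive") tv >= forming_threshold
     else tv <= -forming_threshold)
  supra[!tmap$mask] <- FALSE
  labels <- cc_label(as.vector(supra), as.integer(dim(tv)), as.integer(connectivity))
  nlab <- max(labels)
  if (nlab == 0) return(list())
  out <- vector("list", nlab)
  for (l in seq_len(nlab)) {
    idx <- which(labels == l)
    tvals <- tv[idx]
    peak <- if (direction == "positive") idx[which.max(tvals)] else idx[which.min(tvals)]
    out[[l]] <- structure(list(
      indices = idx, size_voxels = length(idx),
      peak_index = peak,
      peak_vox = drop(index_to_vox(peak, dim(tv))),
      peak_t = tv[peak],
      forming_threshold = forming_threshold, direction = direction,
      connectivity = connectivity, dim = dim(tv)), class = "cluster_result")
  }
  ord <- order(-vapply(out, `[[`, 1L, "size_voxels"),
               vapply(out, function(cl) min(cl$indices), 1L))
  out[ord]
}

#' Binary mask of a cluster
#'
#' @param cluster A `cluster_result`.
#' @return Logical 3D array.
#' @export
cluster_mask <- function(cluster) {
  m <- array(FALSE, dim = cluster$dim)
  m[cluster$indices] <- TRUE
  m
}

#' Cluster-level FWE-corrected p value from random field theory
#'
#' Gaussian-field cluster-extent inference: the t-score forming threshold is
#' converted to an equi-probable Gaussian threshold u, the expected number of
#' clusters E[m] is the resel count times the 3D Euler characteristic
#' density at u, the extent tail follows the exponential form
#' P(n >= k) = exp(-beta k^(2/3)) with beta matched to the expected cluster
#' size, and the corrected p value is the Poisson-clumping probability
#' 1 - exp(-E[m] P(n >= k)). Decreasing in cluster size; increasing in the
#' estimated FWHM at fixed size.
#'
#' @param cluster A `cluster_result`.
#' @param smoothness A `smoothness` estimate.
#' @param df Degrees of freedom of the t map.
#' @return p value in `[0, 1]`; carries attribute `low_threshold_warning`
#'   when the forming threshold is below 1.5, where the extent theory is
#'   unreliable.
#' @export
cluster_p_rft <- function(cluster, smoothness, df) {
  stopifnot(inherits(smoothness, "smoothness"))
  thr <- cluster$forming_threshold
  if (thr <= 0) stop("forming threshold must be positive")
  u <- qnorm(pt(thr, df))
  R <- smoothness$resel_count
  # 3D EC density of a unit Gaussian field
  rho3 <- (4 * log(2))^(3 / 2) / (2 * pi)^2 * (u^2 - 1) * exp(-u^2 / 2)
  Em <- max(R * rho3, 1e-12)
  EN <- R * pnorm(u, lower.tail = FALSE)        # suprathreshold volume, resels
  En <- EN / Em                                 # expected cluster size, resels
  k <- cluster$size_voxels / prod(smoothness$fwhm_voxels)
  beta <- (gamma(5 / 2) / En)^(2 / 3)
  p_one <- exp(-beta * k^(2 / 3))
  p <- 1 - exp(-Em * p_one)
  p <- min(max(p, 0), 1)
  if (thr < 1.5)
    attr(p, "low_threshold_warning") <-
      "forming threshold < 1.5: extent theory unreliable"
  p
}

#' Permutation-based cluster FWE p values
#'
#' Nonparametric reference for the analytic RFT procedure: group labels are
#' permuted, the t map and its supra-threshold clusters are recomputed, and
#' the null distribution of the maximum cluster size calibrates the
#' family-wise-corrected p of each observed cluster. When the number of
#' distinct group-label arrangements is at most `exhaustive_cap`, the null
#' is enumerated exhaustively (the observed labeling included), giving
#' p = #\{null max >= observed size\} / #arrangements; otherwise `n_perm`
#' random arrangements are drawn and p = (1 + #\{null >= obs\}) /
#' (1 + n_perm).
#'
#' @inheritParams voxelwise_ttest
#' @param forming_threshold Cluster-forming T-score threshold.
#' @param connectivity 6, 18 or 26.
#' @param direction `"positive"` (A > B) or `"negative"`.
#' @param n_perm Number of random permutations when not exhaustive.
#' @param seed RNG seed for the random permutations.
#' @param exhaustive_cap Enumerate all arrangements when their count is at
#'   most this value.
#' @return List: `clusters` (observed clusters, each with `p_fwe` added),
#'   `null_max` (null distribution of the maximum cluster size),
#'   `exhaustive`, `n_arrangements`.
#' @export
cluster_p_permutation <- function(maps_A, maps_B, forming_threshold,
                                  connectivity = 18,
                                  direction = c("positive", "negative"),
                                  n_perm = 999, seed = 1L,
                                  exhaustive_cap = 10000) {
  direction <- match.arg(direction)
  tm <- voxelwise_ttest(maps_A, maps_B)
  obs <- form_clusters(tm, forming_threshold, connectivity, direction)
  st <- stack_maps(c(maps_A, maps_B))
  n <- nrow(st$Y); nA <- length(maps_A)
  keepvar <- pooled_t_matrix(st$Y, seq_len(nA))$sp2 > 0
  Y <- st$Y[, keepvar, drop = FALSE]
  mv <- st$mv[keepvar]
  dim3 <- st$dim
  n_all <- choose(n, nA)
  exhaustive <- n_all <= exhaustive_cap
  sets <- if (exhaustive) {
    combn(n, nA, simplify = FALSE)
  } else {
    with_seed(seed, replicate(n_perm, sort(sample.int(n, nA)),
                              simplify = FALSE))
  }
  template <- array(FALSE, dim = dim3)
  null_max <- vapply(sets, function(idx_A) {
    tt <- pooled_t_matrix(Y, idx_A)
    supra <- if (direction == "positive") tt$t >= forming_threshold
             else tt$t <= -forming_threshold
    supra[!is.finite(tt$t)] <- FALSE
    if (!any(supra)) return(0L)
    m <- template
    m[mv[supra]] <- TRUE
    cc_max_size(as.vector(m), as.integer(dim3), as.integer(connectivity))
  }, integer(1))
  for (i in seq_along(obs)) {
    k <- obs[[i]]$size_voxels
    obs[[i]]$p_fwe <- if (exhaustive) mean(null_max >= k)
                      else (1 + sum(null_max >= k)) / (1 + length(null_max))
  }
  list(clusters = obs, null_max = null_max, exhaustive = exhaustive,
       n_arrangements = length(sets))
}

#' Intersection of significant-cluster masks across parameters
#'
#' Voxel-wise logical AND of two or more binary masks on a common grid,
#' reporting the shared region where all parameters show an effect.
#'
#' @param masks List (length >= 2) of logical 3D arrays.
#' @return Logical 3D array; `attr(, "size_voxels")` holds its voxel count.
#' @export
intersect_significant_clusters <- function(masks) {
  if (length(masks) < 2) stop("need at least 2 masks to intersect")
  d <- dim(masks[[1]])
  for (m in masks) stopifnot(identical(dim(m), d))
  out <- Reduce("&", masks)
  attr(out, "size_voxels") <- sum(out)
  out
}

#' One-parameter group comparison with cluster-level correction
#'
#' Convenience wrapper running the full inference chain for one parameter
#' map set and one contrast direction: t map, residual smoothness, cluster
#' formation, and cluster-level FWE p values by random field theory or
#' permutation.
#'
#' @inheritParams cluster_p_permutation
#' @param correction `"rft"` or `"perm"`.
#' @param affine Optional 4x4 affine for reporting peak mm coordinates.
#' @return List: `tmap`, `smoothness`, `clusters` (each with `p_fwe` and,
#'   when `affine` is given, `peak_mm`).
#' @export
group_cluster_analysis <- function(maps_A, maps_B, forming_threshold,
                                   direction = c("positive", "negative"),
                                   connectivity = 18,
                                   correction = c("rft", "perm"),
                                   n_perm = 999, seed = 1L, affine = NULL) {
  direction <- match.arg(direction)
  correction <- match.arg(correction)
  tm <- voxelwise_ttest(maps_A, maps_B)
  if (correction == "rft") {
    resid <- group_residuals(maps_A, maps_B)
    sm <- estimate_smoothness(resid$residuals, resid$mask)
    clusters <- form_clusters(tm, forming_threshold, connectivity, direction)
    for (i in seq_along(clusters))
      clusters[[i]]$p_fwe <- as.numeric(cluster_p_rft(clusters[[i]], sm, tm$df))
  } else {
    pr <- cluster_p_permutation(maps_A, maps_B, forming_threshold,
                                connectivity, direction, n_perm, seed)
    clusters <- pr$clusters
    sm <- NULL
  }
  if (!is.null(affine))
    for (i in seq_along(clusters))
      clusters[[i]]$peak_mm <- drop(vox_to_mm(clusters[[i]]$peak_vox, affine))
  list(tmap = tm, smoothness = sm, clusters = clusters)
}
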