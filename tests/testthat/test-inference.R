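one_voxel_maps <- function(values) {
  lapply(values, function(v) array(v, dim = c(1, 1, 1)))
}

test_that("voxel-wise t test matches the pooled formula", {
  # A = {1,2,3}, B = {3,4,5}: pooled s^2 = 1, se = sqrt(2/3),
  # t = -2 / sqrt(2/3) = -sqrt(6) = -2.449
  tm <- voxelwise_ttest(one_voxel_maps(c(1, 2, 3)), one_voxel_maps(c(3, 4, 5)))
  expect_equal(tm$t[1, 1, 1], -sqrt(6), tolerance = 1e-12)
  expect_equal(tm$df, 4L)

  # identical groups: t = 0 (needs nonzero within-group variance)
  tm0 <- voxelwise_ttest(one_voxel_maps(c(1, 2, 3)), one_voxel_maps(c(1, 2, 3)))
  expect_equal(tm0$t[1, 1, 1], 0)

  expect_error(voxelwise_ttest(one_voxel_maps(1), one_voxel_maps(c(1, 2))),
               "at least 2")
})

test_that("t map flips sign under group swap and ignores within-group order", {
  set.seed(12)
  d <- c(6, 6, 4)
  A <- replicate(5, array(rnorm(prod(d)), dim = d), simplify = FALSE)
  B <- replicate(5, array(rnorm(prod(d)), dim = d), simplify = FALSE)
  t1 <- voxelwise_ttest(A, B)
  t2 <- voxelwise_ttest(B, A)
  expect_equal(t1$t, -t2$t)
  t3 <- voxelwise_ttest(A[c(3, 1, 5, 2, 4)], B)
  expect_equal(t1$t, t3$t)
})

test_that("zero-variance voxels leave the analysis mask", {
  d <- c(2, 1, 1)
  A <- replicate(3, array(c(5, 1), dim = d), simplify = FALSE)
  A <- lapply(seq_along(A), function(i) {
    m <- A[[i]]; m[2] <- i; m
  })
  B <- replicate(3, array(c(5, 0), dim = d), simplify = FALSE)
  tm <- voxelwise_ttest(A, B)
  expect_false(tm$mask[1, 1, 1])   # constant 5 in both groups
  expect_true(tm$mask[2, 1, 1])
  expect_true(is.na(tm$t[1, 1, 1]))
})

test_that("smoothness estimator recovers a known FWHM and scales resels", {
  dim3 <- c(24L, 24L, 12L)
  fwhm_true <- 8 / c(3.75, 3.75, 5)
  set.seed(21)
  rel_err <- replicate(25, {
    A <- replicate(6, smooth_noise_field(dim3, fwhm_true), simplify = FALSE)
    B <- replicate(6, smooth_noise_field(dim3, fwhm_true), simplify = FALSE)
    res <- group_residuals(A, B)
    sm <- estimate_smoothness(res$residuals, res$mask)
    max(abs(sm$fwhm_voxels - fwhm_true) / fwhm_true)
  })
  expect_lt(median(rel_err), 0.15)

  # white noise: estimated FWHM collapses toward the voxel scale, far below
  # any smoothed field
  A <- replicate(6, array(rnorm(prod(dim3)), dim = dim3), simplify = FALSE)
  B <- replicate(6, array(rnorm(prod(dim3)), dim = dim3), simplify = FALSE)
  res <- group_residuals(A, B)
  smw <- estimate_smoothness(res$residuals, res$mask)
  expect_true(all(smw$fwhm_voxels < 1))

  # doubling the mask volume at fixed smoothness doubles the resel count
  flds <- replicate(6, smooth_noise_field(c(24L, 24L, 24L), fwhm_true),
                    simplify = FALSE)
  flds2 <- replicate(6, smooth_noise_field(c(24L, 24L, 24L), fwhm_true),
                     simplify = FALSE)
  res <- group_residuals(flds, flds2)
  half <- array(FALSE, dim = c(24, 24, 24)); half[, , 1:12] <- TRUE
  sm_full <- estimate_smoothness(res$residuals, res$mask)
  sm_half <- estimate_smoothness(res$residuals, res$mask & half)
  ratio <- sm_full$resel_count / sm_half$resel_count
  expect_lt(abs(ratio - 2), 0.35)

  expect_error(estimate_smoothness(res$residuals[1:2], res$mask), "at least 3")
  flat <- replicate(4, array(1, dim = dim3), simplify = FALSE)
  expect_error(estimate_smoothness(flat, array(TRUE, dim = dim3)), "flat|smoothness")
})

test_that("cluster formation handles trivial and forced cases", {
  z <- array(0, dim = c(8, 8, 4))
  expect_length(form_clusters(as_tmap(z), 2.0), 0)

  blk <- z
  blk[3:4, 3:4, 2:3] <- 3.0
  cl <- form_clusters(as_tmap(blk), 2.0)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$size_voxels, 8L)
  expect_equal(cl[[1]]$peak_t, 3.0)

  # negative direction picks up the mirrored cluster
  cln <- form_clusters(as_tmap(-blk), 2.0, direction = "negative")
  expect_length(cln, 1)
  expect_equal(cln[[1]]$peak_t, -3.0)
})

test_that("cluster decomposition equals the union-find oracle and partitions", {
  set.seed(33)
  for (i in 1:12) {
    arr <- array(rnorm(12 * 12 * 6), dim = c(12, 12, 6))
    for (conn in c(6, 18, 26)) {
      cl <- form_clusters(as_tmap(arr), 1.5, connectivity = conn)
      expect_identical(canonical_clusters(cl),
                       oracle_components(arr >= 1.5, conn))
      # partition: disjoint members, union = supra-threshold set
      all_idx <- unlist(lapply(cl, `[[`, "indices"))
      expect_false(anyDuplicated(all_idx) > 0)
      expect_setequal(all_idx, which(arr >= 1.5))
    }
  }
})

test_that("RFT cluster p behaves monotonically and approaches 1 at size 0", {
  sm <- structure(list(fwhm_voxels = c(2.1, 2.1, 1.6),
                       resel_count = 24 * 24 * 12 / prod(c(2.1, 2.1, 1.6))),
                  class = "smoothness")
  mk <- function(size) structure(list(size_voxels = size,
                                      forming_threshold = 2.0),
                                 class = "cluster_result")
  sizes <- c(1, 5, 20, 80, 200, 500)
  ps <- vapply(sizes, function(s) as.numeric(cluster_p_rft(mk(s), sm, 20)),
               numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_gt(ps[1], 0.999)

  # at fixed size, smoother fields make the same extent less surprising
  sm_smooth <- structure(list(fwhm_voxels = c(3.5, 3.5, 2.5),
                              resel_count = 24 * 24 * 12 /
                                prod(c(3.5, 3.5, 2.5))), class = "smoothness")
  expect_gt(as.numeric(cluster_p_rft(mk(150), sm_smooth, 20)),
            as.numeric(cluster_p_rft(mk(150), sm, 20)))

  # low forming thresholds carry a reliability warning; normal ones do not
  low <- structure(list(size_voxels = 100, forming_threshold = 1.2),
                   class = "cluster_result")
  expect_match(attr(cluster_p_rft(low, sm, 20), "low_threshold_warning"),
               "unreliable")
  expect_null(attr(cluster_p_rft(mk(100), sm, 20), "low_threshold_warning"))
})

test_that("permutation p values use the exhaustive null when feasible", {
  set.seed(44)
  d <- c(8, 8, 4)
  eff <- array(0, dim = d); eff[3:6, 3:6, 2:3] <- 5
  A <- replicate(3, eff + array(rnorm(prod(d), 0, 0.5), dim = d),
                 simplify = FALSE)
  B <- replicate(3, array(rnorm(prod(d), 0, 0.5), dim = d), simplify = FALSE)
  pr <- cluster_p_permutation(A, B, 2.0, 18, "positive", seed = 1)
  expect_true(pr$exhaustive)
  expect_equal(pr$n_arrangements, choose(6, 3))
  # strong planted effect: the big cluster attains the minimum possible p
  expect_equal(pr$clusters[[1]]$p_fwe, 1 / 20)
})

test_that("RFT and permutation order clusters identically", {
  set.seed(55)
  d <- c(16, 16, 8)
  base <- array(0, dim = d)
  base[3:7, 3:7, 2:5] <- 1.6        # strong planted effect
  base[12:14, 12:14, 6:7] <- 1.2    # weaker, smaller one
  A <- replicate(6, base + smooth_noise_field(d, c(2, 2, 1.5)) * 0.8,
                 simplify = FALSE)
  B <- replicate(6, smooth_noise_field(d, c(2, 2, 1.5)) * 0.8,
                 simplify = FALSE)
  an <- group_cluster_analysis(A, B, 2.0, "positive", 18, "rft")
  pr <- cluster_p_permutation(A, B, 2.0, 18, "positive", n_perm = 99,
                              seed = 3)
  key <- function(cl) vapply(cl, function(x) min(x$indices), numeric(1))
  expect_identical(key(an$clusters), key(pr$clusters))
  # both corrections are monotone in extent, so p ranks agree (up to ties):
  # clusters arrive sorted by size descending
  p_rft <- vapply(an$clusters, `[[`, 1.0, "p_fwe")
  p_prm <- vapply(pr$clusters, `[[`, 1.0, "p_fwe")
  expect_true(all(diff(p_rft) >= -1e-12))
  expect_true(all(diff(p_prm) >= -1e-12))
  expect_identical(which.min(p_rft), which.min(p_prm))
})

test_that("cluster mask intersection is the voxel-wise AND", {
  d <- c(4, 4, 2)
  m1 <- array(FALSE, dim = d); m1[1:2, , ] <- TRUE
  m2 <- array(FALSE, dim = d); m2[2:3, , ] <- TRUE
  inter <- intersect_significant_clusters(list(m1, m2))
  expect_equal(sum(inter), sum(m1 & m2))
  expect_equal(attr(inter, "size_voxels"), sum(inter))
  expect_identical(intersect_significant_clusters(list(m1, m1)),
                   structure(m1, size_voxels = sum(m1)))
  m3 <- array(FALSE, dim = d); m3[4, , ] <- TRUE
  expect_equal(sum(intersect_significant_clusters(list(m1, m3))), 0)
  # nested masks intersect to the smaller
  m4 <- m1; m4[1, , ] <- FALSE
  expect_equal(sum(intersect_significant_clusters(list(m1, m4))), sum(m4))
  expect_error(intersect_significant_clusters(list(m1)), "at least 2")
})
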