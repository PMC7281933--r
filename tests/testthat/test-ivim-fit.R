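b15 <- b15_schedule

test_that("forward model matches hand-evaluated values", {
  # direct evaluation of the bi-exponential:
  # 0.9 exp(-1) + 0.1 exp(-10) = 0.3310960370
  expect_equal(ivim_signal(0.1, 1e-3, 9e-3, 1000), 0.3310960370472744,
               tolerance = 1e-12)
  expect_identical(ivim_signal(0.07, 0.9e-3, 12e-3, 0), 1)
  # v_bw = 0 reduces to a mono-exponential
  expect_equal(ivim_signal(0, 1.2e-3, 50e-3, b15), exp(-b15 * 1.2e-3))
  # D*-only fast-rate convention differs by exactly D in the fast exponent
  expect_equal(ivim_signal(0.1, 1e-3, 9e-3, 1000, fast_rate = "dstar_only"),
               ivim_signal(0.1, 1e-3, 8e-3, 1000), tolerance = 1e-15)
  expect_error(ivim_signal(0.1, 1e-3, 9e-3, -5), ">= 0")
})

test_that("signal is strictly decreasing in b for D > 0", {
  set.seed(1)
  for (i in 1:20) {
    v <- runif(1, 0, 0.3); D <- runif(1, 1e-4, 3e-3)
    Ds <- runif(1, D, 0.1)
    y <- ivim_signal(v, D, Ds, seq(0, 1000, by = 50))
    expect_true(all(diff(y) < 0))
  }
})

test_that("mono-exponential tail fit is exact on its own model", {
  y <- exp(-b15 * 0.8e-3)
  f <- fit_monoexp_tail(y, b15, b_cut = 200)
  expect_equal(f$D, 0.8e-3, tolerance = 1e-12)
  expect_equal(f$amplitude, 1, tolerance = 1e-12)

  const <- rep(1, length(b15))
  fc <- fit_monoexp_tail(const, b15, b_cut = 200)
  expect_equal(fc$D, 0, tolerance = 1e-15)
  expect_equal(fc$amplitude, 1, tolerance = 1e-15)

  expect_error(fit_monoexp_tail(c(1, 0, 0), c(0, 500, 1000), 200),
               "at least 2")
})

test_that("tail D bias from residual perfusion is below 2% at b_cut 200", {
  y <- ivim_signal(0.05, 0.8e-3, 10e-3, b15)
  f <- fit_monoexp_tail(y, b15, b_cut = 200)
  expect_lt(abs(f$D - 0.8e-3) / 0.8e-3, 0.02)
  expect_gt(f$D, 0.8e-3)   # perfusion remnant biases the slope upward
})

test_that("voxel fit matches an independent grid-search oracle", {
  cases <- list(c(0.05, 0.8e-3, 10e-3), c(0.15, 1.5e-3, 30e-3),
                c(0.28, 0.4e-3, 5e-3))
  for (cs in cases) {
    y <- ivim_signal(cs[1], cs[2], cs[3], b15)
    fit <- fit_ivim_voxel(y, b15, "full_nls")
    orc <- oracle_ivim_fit(y, b15)
    # grid refinement resolves the same basin, not machine precision: 5%
    expect_equal(fit$params$v_bw, orc$v_bw, tolerance = 5e-2)
    expect_equal(fit$params$D, orc$D, tolerance = 5e-2)
    expect_equal(fit$params$D_star, orc$D_star, tolerance = 5e-2)
    # the analytic fit must be at least as good as the oracle's best rss
    expect_lte(fit$residual_norm^2, orc$rss + 1e-12)
  }
})

test_that("degenerate zero-perfusion voxel is flagged", {
  y <- exp(-b15 * 1e-3)
  f <- fit_ivim_voxel(y, b15, "full_nls")
  expect_lt(f$params$v_bw, 1e-6)
  expect_equal(f$params$D, 1e-3, tolerance = 1e-9)
  expect_true(f$dstar_unidentifiable)
})

test_that("full fit never has larger residual than the segmented start", {
  set.seed(8)
  for (i in 1:30) {
    v <- runif(1, 0.01, 0.3); D <- runif(1, 1e-4, 3e-3)
    Ds <- runif(1, max(D, 1e-3), 0.1)
    y <- ivim_signal(v, D, Ds, b15) + rnorm(length(b15), 0, 0.02)
    y[1] <- 1
    y <- pmax(y, 1e-6)
    f <- fit_ivim_voxel(y, b15, "full_nls")
    expect_lte(f$residual_norm, f$segmented_residual_norm + 1e-12)
  }
})

test_that("volume fit reduces to the voxel fit and respects masks", {
  spec <- tiny_spec(noise_sigma = 0, field_sd = list(v_bw = 0, D = 0,
                                                     D_star = 0),
                    between_subject_sd = list(v_bw = 0, D = 0, D_star = 0))
  tr <- build_true_fields(spec, "patient", subject_seed = 1L)
  dwi <- simulate_dwi(tr, spec, n_directions = 1, seed = 1L)
  norm <- normalize_to_b0(average_directions(dwi))
  maps <- fit_ivim_volume(norm, "full_nls")

  # two-region noiseless phantom: maps are piecewise constant and the
  # boundary coincides with the effect region
  p <- spec$baseline_params; dl <- spec$effect_deltas
  expect_equal(maps$v_bw[!spec$effect_region],
               rep(p$v_bw, sum(!spec$effect_region)), tolerance = 1e-5)
  expect_equal(maps$v_bw[spec$effect_region],
               rep(p$v_bw + dl$v_bw, sum(spec$effect_region)),
               tolerance = 1e-5)
  expect_equal(maps$D_star[spec$effect_region],
               rep(p$D_star + dl$D_star, sum(spec$effect_region)),
               tolerance = 1e-4)
  # flow is exactly the elementwise product
  expect_identical(maps$flow, maps$v_bw * maps$D_star)

  # masked-out voxels are NA in every map
  norm2 <- norm
  norm2$brain_mask[1, 1, 1] <- FALSE
  maps2 <- fit_ivim_volume(norm2)
  expect_true(is.na(maps2$v_bw[1, 1, 1]))
  expect_true(is.na(maps2$flow[1, 1, 1]))
  expect_false(maps2$mask[1, 1, 1])

  norm3 <- norm
  norm3$brain_mask[] <- FALSE
  expect_error(fit_ivim_volume(norm3), "empty")
})

test_that("fast-rate convention shifts fitted D* by exactly D", {
  y_sum <- ivim_signal(0.1, 1e-3, 9e-3, b15, fast_rate = "sum")
  f_sum <- fit_ivim_voxel(y_sum, b15, "full_nls",
                          ivim_fit_options(fast_rate = "sum"))
  f_dso <- fit_ivim_voxel(y_sum, b15, "full_nls",
                          ivim_fit_options(fast_rate = "dstar_only"))
  expect_equal(f_sum$params$D_star, 9e-3, tolerance = 1e-6)
  expect_equal(f_dso$params$D_star, 10e-3, tolerance = 1e-6)
})
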