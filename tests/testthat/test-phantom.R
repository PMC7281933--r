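test_that("spec validation rejects unphysical parameters", {
  expect_error(phantom_spec(b_schedule = c(0, 10, 10, 100)),
               "strictly increasing")
  expect_error(phantom_spec(b_schedule = c(5, 10, 100, 500)),
               "start at 0")
  expect_error(phantom_spec(n_per_group = 1), "n_per_group")
  expect_error(phantom_spec(noise_sigma = -0.1), "noise_sigma")
  # delta pushing D above D* inside the region names the offender
  expect_error(
    phantom_spec(effect_deltas = list(v_bw = 0, D = 2e-3, D_star = -9.5e-3)),
    "D_star")
  expect_error(
    phantom_spec(effect_deltas = list(v_bw = -0.2, D = 0, D_star = 0)),
    "v_bw")
})

test_that("true fields are deterministic, physical, and group shifts are local", {
  spec <- tiny_spec(seed = 5L)
  a <- build_true_fields(spec, "patient", subject_seed = 11L)
  b <- build_true_fields(spec, "patient", subject_seed = 11L)
  expect_identical(a$fields, b$fields)
  for (f in a$fields) expect_true(all(is.finite(f)))
  expect_true(all(a$fields$v_bw >= 0 & a$fields$v_bw <= 1))
  expect_true(all(a$fields$D >= 0))
  expect_true(all(a$fields$D_star >= a$fields$D))
  expect_equal(a$fields$flow, a$fields$v_bw * a$fields$D_star)

  # zero effect deltas: patient and control draws coincide at equal seeds
  spec0 <- tiny_spec(effect_deltas = list(v_bw = 0, D = 0, D_star = 0))
  p0 <- build_true_fields(spec0, "patient", subject_seed = 3L)
  c0 <- build_true_fields(spec0, "control", subject_seed = 3L)
  expect_identical(p0$fields, c0$fields)
})

test_that("effect deltas shift the region mean by the requested amount", {
  # sample-mean check over repeated subjects: region mean ~ baseline + delta,
  # outside mean ~ baseline, both within the between-subject spread
  spec <- tiny_spec(baseline_params = list(v_bw = 0.05, D = 0.8e-3,
                                           D_star = 10e-3),
                    effect_deltas = list(v_bw = -0.02, D = 0, D_star = 0))
  n <- 25
  inside <- outside <- numeric(n)
  for (i in seq_len(n)) {
    tr <- build_true_fields(spec, "patient", subject_seed = 100L + i)
    inside[i] <- mean(tr$fields$v_bw[spec$effect_region])
    outside[i] <- mean(tr$fields$v_bw[!spec$effect_region])
  }
  tol <- 3 * spec$between_subject_sd$v_bw / sqrt(n)
  expect_lt(abs(mean(inside) - 0.03), tol)
  expect_lt(abs(mean(outside) - 0.05), tol)
})

test_that("noiseless forward simulation reproduces the bi-exponential signal", {
  spec <- tiny_spec(noise_sigma = 0, field_sd = list(v_bw = 0, D = 0,
                                                     D_star = 0),
                    between_subject_sd = list(v_bw = 0, D = 0, D_star = 0))
  tr <- build_true_fields(spec, "control", subject_seed = 1L)
  dwi <- simulate_dwi(tr, spec, n_directions = 1, seed = 1L)
  # b = 0 volume equals S0 exactly everywhere
  expect_equal(as.vector(dwi$signal[, , , 1, 1]),
               rep(spec$s0, prod(spec$grid_shape)))
  # a voxel's series equals the hand-evaluated model
  p <- spec$baseline_params
  expect_equal(dwi$signal[3, 4, 2, , 1],
               spec$s0 * ivim_signal(p$v_bw, p$D, p$D_star, spec$b_schedule),
               tolerance = 1e-12)
})

test_that("Rician noise has calibrated scale and floor", {
  # recovered Gaussian-component sd from repeated high-SNR acquisitions
  sigma <- 0.02; s0 <- 1
  set.seed(31)
  x <- ivimtools:::rician_noise(rep(s0, 2e4), sigma)
  expect_lt(abs(sd(x) - sigma) / sigma, 0.05)
  # Rician floor at zero signal: mean -> sigma * sqrt(pi / 2)
  z <- ivimtools:::rician_noise(rep(0, 2e4), sigma)
  expect_lt(abs(mean(z) - sigma * sqrt(pi / 2)) / (sigma * sqrt(pi / 2)),
            0.05)
  # high-SNR mean approaches the noiseless signal
  expect_lt(abs(mean(x) - s0), 3 * sigma / sqrt(2e4) + sigma^2)
})

test_that("cohorts are reproducible and covariates track regional truth", {
  spec <- tiny_spec(seed = 9L)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$dwi[[1]]$signal, b$dwi[[1]]$signal)
  expect_identical(names(a$dwi), a$cohort$subject_id)
  expect_equal(nrow(a$cohort), 2 * spec$n_per_group)

  # zero covariate noise, slope -1: correlation with regional mean exactly -1
  spec2 <- tiny_spec(seed = 2L, covariate_model = list(
    cv = list(parameter = "flow", slope = -1, intercept = 0, noise_sd = 0)))
  coh <- generate_cohort(spec2, simulate = FALSE)
  reg <- vapply(coh$truth, function(tr)
    mean(tr$fields$flow[spec2$effect_region]), numeric(1))
  expect_equal(cor(reg, coh$cohort$cv), -1)

  # truth-only path agrees with the full run
  full <- generate_cohort(spec2)
  expect_identical(coh$cohort, full$cohort)
})
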