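#' Bi-exponential IVIM model and parameter estimation
#'
#' The intravoxel incoherent motion model describes the fractional
#' diffusion-weighted signal as a mixture of two exponentially decaying
#' compartments: water diffusing in bulk tissue (coefficient D) and water
#' pseudo-diffusing through randomly oriented microvasculature (coefficient
#' D*, fraction v_bw):
#'
#'   S(b)/S0 = (1 - v_bw) exp(-b D) + v_bw exp(-b (D + D*))
#'
#' The derived product D* x v_bw indexes blood flow. The fast-compartment
#' rate is written as D + D* by default (`fast_rate = "sum"`); part of the
#' IVIM literature uses D* alone as the fast rate, available as
#' `fast_rate = "dstar_only"`. Reported D* differs between the conventions by
#' exactly D.
#'
#' @name ivim_model
NULL

#' Evaluate the IVIM forward model
#'
#' @param v_bw Blood-water fraction in `[0, 1]` (recycled).
#' @param D Parenchymal diffusion coefficient, mm^2/s (recycled).
#' @param D_star Pseudo-diffusion coefficient, mm^2/s (recycled).
#' @param b b value(s), s/mm^2, >= 0.
#' @param fast_rate Fast-compartment decay rate convention: `"sum"` uses
#'   D + D*, `"dstar_only"` uses D* alone.
#' @return Fractional signal in `(0, 1]`; exactly 1 at b = 0.
#' @export
ivim_signal <- function(v_bw, D, D_star, b, fast_rate = c("sum", "dstar_only")) {
  fast_rate <- match.arg(fast_rate)
  if (any(b < 0)) stop("b values must be >= 0")
  rate2 <- if (fast_rate == "sum") D + D_star else D_star
  (1 - v_bw) * exp(-b * D) + v_bw * exp(-b * rate2)
}

#' Fitting options for the IVIM estimators
#'
#' @param b_cut Tail cut-off for the segmented mono-exponential step,
#'   s/mm^2. Default 200: for D* >= 10e-3 mm^2/s the perfusion compartment
#'   has decayed by at least exp(-2) there.
#' @param v_bw_bounds,D_bounds Parameter box constraints (physiological brain
#'   ranges; prevent compartment swapping).
#' @param D_star_max Upper bound on D*, mm^2/s. The lower bound is D itself.
#' @param fast_rate Fast-rate convention, see [ivim_signal()].
#' @param grid_size Number of log-spaced D* candidates in the profiled grid
#'   search that initializes the refinement.
#' @param max_iter Maximum Gauss-Newton iterations per voxel.
#' @param ftol Convergence tolerance on the residual sum of squares.
#' @return List of options for [fit_ivim_voxel()] / [fit_ivim_volume()].
#' @export
ivim_fit_options <- function(b_cut = 200,
                             v_bw_bounds = c(0, 0.3),
                             D_bounds = c(0, 3e-3),
                             D_star_max = 0.1,
                             fast_rate = c("sum", "dstar_only"),
                             grid_size = 40L,
                             max_iter = 200L,
                             ftol = 1e-10) {
  fast_rate <- match.arg(fast_rate)
  list(b_cut = b_cut, v_bw_bounds = v_bw_bounds, D_bounds = D_bounds,
       D_star_max = D_star_max, fast_rate = fast_rate,
       grid_size = as.integer(grid_size), max_iter = as.integer(max_iter),
       ftol = ftol)
}

#' Log-linear mono-exponential fit of the high-b tail
#'
#' Ordinary least squares of log signal against b over the sub-schedule with
#' b >= b_cut, where the perfusion compartment has essentially decayed. The
#' slope magnitude estimates D; the back-extrapolated amplitude
#' exp(intercept) estimates the tissue fraction 1 - v_bw.
#'
#' @param signal Fractional signal series.
#' @param b_schedule Matching b values.
#' @param b_cut Tail cut-off, s/mm^2.
#' @return List with `D`, `amplitude`, `n_points`.
#' @export
fit_monoexp_tail <- function(signal, b_schedule, b_cut = 200) {
  keep <- b_schedule >= b_cut & signal > 0
  if (sum(keep) < 2)
    stop("need at least 2 positive signals at b >= b_cut")
  x <- b_schedule[keep]
  y <- log(signal[keep])
  sx <- mean(x); sy <- mean(y)
  slope <- sum((x - sx) * (y - sy)) / sum((x - sx)^2)
  list(D = -slope, amplitude = exp(sy - slope * sx), n_points = sum(keep))
}

# --- vectorized engine -------------------------------------------------------
# All voxels are fitted simultaneously: Y is V x B fractional signal. The
# segmented path is (1) closed-form log-linear tail fit for D, (2) profiled
# grid search over shared D* candidates with the closed-form optimal v_bw per
# voxel, (3) damped Gauss-Newton refinement of (v_bw, D*). The full path adds
# D to the refinement, started from the segmented solution.

ivim_design <- function(D, D_star, b, fast_rate) {
  E1 <- exp(-outer(D, b))
  rate2 <- if (fast_rate == "sum") D + D_star else D_star
  E2 <- exp(-outer(rate2, b))
  list(E1 = E1, E2 = E2)
}

ivim_rss <- function(v, D, Ds, Y, b, fast_rate) {
  des <- ivim_design(D, Ds, b, fast_rate)
  model <- (1 - v) * des$E1 + v * des$E2
  rowSums((model - Y)^2)
}

# Closed-form tail fit for all rows of Y at once. Non-positive tail signals
# are excluded pointwise; voxels with < 2 usable points are flagged invalid.
tail_fit_matrix <- function(Y, b, b_cut) {
  tcols <- which(b >= b_cut)
  Yt <- Y[, tcols, drop = FALSE]
  w <- (Yt > 0) * 1
  nw <- rowSums(w)
  valid <- nw >= 2
  ly <- ifelse(Yt > 0, suppressWarnings(log(pmax(Yt, 1e-300))), 0)
  x <- matrix(b[tcols], nrow = nrow(Y), ncol = length(tcols), byrow = TRUE)
  swx <- rowSums(w * x); swy <- rowSums(w * ly)
  sxx <- rowSums(w * x * x); sxy <- rowSums(w * x * ly)
  denom <- sxx - swx^2 / pmax(nw, 1)
  slope <- (sxy - swx * swy / pmax(nw, 1)) / ifelse(denom > 0, denom, 1)
  slope[denom <= 0] <- 0
  intercept <- (swy - slope * swx) / pmax(nw, 1)
  list(D = -slope, amplitude = exp(intercept), valid = valid)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Profiled grid search over D*: for each shared candidate, v_bw has a closed
# form (linear sub-problem), clamped to its bounds; infeasible candidates
# (D* < D) are skipped per voxel. A candidate at exactly D* = D guarantees
# feasibility everywhere.
dstar_grid_search <- function(Y, b, D, opt) {
  V <- nrow(Y)
  cand <- exp(seq(log(1e-4), log(opt$D_star_max), length.out = opt$grid_size))
  best_rss <- rep(Inf, V)
  best_v <- rep(0, V)
  best_ds <- pmax(D, 1e-6)
  E1 <- exp(-outer(D, b))
  eval_candidate <- function(Ds_vec) {
    rate2 <- if (opt$fast_rate == "sum") D + Ds_vec else Ds_vec
    E2 <- exp(-outer(rate2, b))
    diffE <- E2 - E1
    den <- rowSums(diffE^2)
    v <- clamp(rowSums((Y - E1) * diffE) / ifelse(den > 0, den, 1),
               opt$v_bw_bounds[1], opt$v_bw_bounds[2])
    rss <- rowSums((E1 + v * diffE - Y)^2)
    list(v = v, rss = rss)
  }
  for (k in seq_along(cand)) {
    feasible <- cand[k] >= D
    if (!any(feasible)) next
    res <- eval_candidate(rep(cand[k], V))
    take <- feasible & res$rss < best_rss
    best_rss[take] <- res$rss[take]
    best_v[take] <- res$v[take]
    best_ds[take] <- cand[k]
  }
  res0 <- eval_candidate(pmax(D, 1e-6))        # D* = D fallback candidate
  take <- res0$rss < best_rss
  best_rss[take] <- res0$rss[take]
  best_v[take] <- res0$v[take]
  best_ds[take] <- pmax(D, 1e-6)[take]
  list(v = best_v, D_star = best_ds, rss = best_rss)
}

# Damped Gauss-Newton over (v_bw, D*) or (v_bw, D, D*), vectorized across
# voxels with per-voxel step halving; steps are only accepted when they do
# not increase the residual sum of squares, so refinement never degrades the
# starting point.
gauss_newton_refine <- function(Y, b, v, D, Ds, opt, fit_D = FALSE) {
  V <- nrow(Y)
  rss <- ivim_rss(v, D, Ds, Y, b, opt$fast_rate)
  n_iter <- rep(0L, V)
  converged <- rep(FALSE, V)
  bm <- matrix(b, nrow = V, ncol = length(b), byrow = TRUE)
  for (iter in seq_len(opt$max_iter)) {
    des <- ivim_design(D, Ds, b, opt$fast_rate)
    model <- (1 - v) * des$E1 + v * des$E2
    r <- model - Y
    Jv <- des$E2 - des$E1
    Js <- -v * bm * des$E2
    if (fit_D) {
      Jd <- if (opt$fast_rate == "sum") -bm * model else -(1 - v) * bm * des$E1
      a11 <- rowSums(Jv^2); a12 <- rowSums(Jv * Jd); a13 <- rowSums(Jv * Js)
      a22 <- rowSums(Jd^2); a23 <- rowSums(Jd * Js); a33 <- rowSums(Js^2)
      g1 <- rowSums(Jv * r); g2 <- rowSums(Jd * r); g3 <- rowSums(Js * r)
      # Levenberg damping keeps the 3x3 system well-posed at degenerate voxels
      lam <- 1e-12 + 1e-8 * (a11 + a22 + a33)
      a11 <- a11 + lam; a22 <- a22 + lam; a33 <- a33 + lam
      det3 <- a11 * (a22 * a33 - a23^2) - a12 * (a12 * a33 - a23 * a13) +
        a13 * (a12 * a23 - a22 * a13)
      det3[abs(det3) < 1e-300] <- 1
      dv <- -((a22 * a33 - a23^2) * g1 - (a12 * a33 - a13 * a23) * g2 +
                (a12 * a23 - a13 * a22) * g3) / det3
      dd <- -(-(a12 * a33 - a23 * a13) * g1 + (a11 * a33 - a13^2) * g2 -
                (a11 * a23 - a12 * a13) * g3) / det3
      ds <- -((a12 * a23 - a22 * a13) * g1 - (a11 * a23 - a12 * a13) * g2 +
                (a11 * a22 - a12^2) * g3) / det3
    } else {
      a11 <- rowSums(Jv^2); a12 <- rowSums(Jv * Js); a22 <- rowSums(Js^2)
      g1 <- rowSums(Jv * r); g2 <- rowSums(Js * r)
      lam <- 1e-12 + 1e-8 * (a11 + a22)
      a11 <- a11 + lam; a22 <- a22 + lam
      det2 <- a11 * a22 - a12^2
      det2[abs(det2) < 1e-300] <- 1
      dv <- -(a22 * g1 - a12 * g2) / det2
      ds <- -(a11 * g2 - a12 * g1) / det2
      dd <- rep(0, V)
    }
    step <- rep(1, V)
    new_rss <- rss
    nv <- v; nd <- D; ns <- Ds
    pending <- rep(TRUE, V)
    for (halving in 1:8) {
      cv <- clamp(v + step * dv, opt$v_bw_bounds[1], opt$v_bw_bounds[2])
      cd <- if (fit_D) clamp(D + step * dd, opt$D_bounds[1], opt$D_bounds[2]) else D
      cs <- clamp(Ds + step * ds, cd, opt$D_star_max)
      crss <- ivim_rss(cv, cd, cs, Y, b, opt$fast_rate)
      ok <- pending & (crss <= rss)
      nv[ok] <- cv[ok]; nd[ok] <- cd[ok]; ns[ok] <- cs[ok]
      new_rss[ok] <- crss[ok]
      pending <- pending & !ok
      if (!any(pending)) break
      step[pending] <- step[pending] / 2
    }
    improved <- new_rss < rss - opt$ftol
    n_iter[improved] <- iter
    newly_conv <- !converged & !improved
    converged[newly_conv] <- TRUE
    v <- nv; D <- nd; Ds <- ns; rss <- new_rss
    if (all(converged)) break
  }
  list(v = v, D = D, D_star = Ds, rss = rss, n_iter = n_iter,
       converged = converged | n_iter < opt$max_iter)
}

# Shared engine: Y is V x B normalized signal. Returns vectors per voxel.
fit_ivim_matrix <- function(Y, b, method = c("segmented", "full_nls"),
                            options = ivim_fit_options()) {
  method <- match.arg(method)
  opt <- options
  valid_pts <- rowSums(Y > 0 & is.finite(Y))
  tail <- tail_fit_matrix(Y, b, opt$b_cut)
  valid <- tail$valid & valid_pts >= 4
  D <- clamp(tail$D, opt$D_bounds[1], opt$D_bounds[2])
  D[!valid] <- 0
  grid <- dstar_grid_search(Y, b, D, opt)
  seg <- gauss_newton_refine(Y, b, grid$v, D, grid$D_star, opt, fit_D = FALSE)
  seg_rss <- seg$rss
  if (method == "full_nls") {
    full <- gauss_newton_refine(Y, b, seg$v, seg$D, seg$D_star, opt,
                                fit_D = TRUE)
    # acceptance-only steps guarantee rss <= segmented rss
    res <- full
  } else res <- seg
  list(v_bw = res$v, D = res$D, D_star = res$D_star,
       flow = res$v * res$D_star,
       residual_norm = sqrt(res$rss), segmented_residual_norm = sqrt(seg_rss),
       converged = res$converged & valid, n_iter = res$n_iter,
       valid = valid, method = method)
}

#' Fit the IVIM model to one voxel's signal series
#'
#' Segmented method: D from the log-linear high-b tail, then v_bw and D* by
#' bounded least squares on the full curve with D held fixed. Full method
#' (`"full_nls"`): simultaneous bounded Levenberg-Marquardt over
#' (v_bw, D, D*) started from the segmented solution (and never worse than
#' it). Non-convergence and degenerate inputs are flagged on the result, not
#' thrown.
#'
#' @param signal Normalized (fractional) signal series.
#' @param b_schedule Matching b values; the first must be 0.
#' @param method `"segmented"` or `"full_nls"`.
#' @param options See [ivim_fit_options()].
#' @return A `fit_result`: `params` (v_bw, D, D_star, flow),
#'   `residual_norm`, `converged`, `method`, `n_iter`,
#'   `dstar_unidentifiable` (TRUE when v_bw is estimated below 0.005, where
#'   the data carry no information on D*).
#' @export
fit_ivim_voxel <- function(signal, b_schedule,
                           method = c("segmented", "full_nls"),
                           options = ivim_fit_options()) {
  method <- match.arg(method)
  if (length(signal) != length(b_schedule))
    stop("series length does not match b_schedule")
  if (sum(signal > 0 & is.finite(signal)) < 4) {
    return(structure(list(
      params = list(v_bw = NA_real_, D = NA_real_, D_star = NA_real_,
                    flow = NA_real_),
      residual_norm = NA_real_, converged = FALSE, method = method,
      n_iter = 0L, dstar_unidentifiable = NA), class = "fit_result"))
  }
  Y <- matrix(signal, nrow = 1)
  res <- fit_ivim_matrix(Y, b_schedule, method, options)
  if (method == "full_nls" && requireNamespace("minpack.lm", quietly = TRUE)) {
    # polish with bounded Levenberg-Marquardt on (v_bw, D, g = D* - D >= 0)
    opt <- options
    fr <- opt$fast_rate
    resid_fun <- function(p)
      ivim_signal(p[1], p[2], p[2] + p[3], b_schedule, fr) - signal
    start <- c(res$v_bw, res$D, max(res$D_star - res$D, 0))
    lm <- try(minpack.lm::nls.lm(
      par = start, fn = resid_fun,
      lower = c(opt$v_bw_bounds[1], opt$D_bounds[1], 0),
      upper = c(opt$v_bw_bounds[2], opt$D_bounds[2], opt$D_star_max),
      control = minpack.lm::nls.lm.control(
        ftol = 1e-15, ptol = 1e-15, maxiter = opt$max_iter)), silent = TRUE)
    if (!inherits(lm, "try-error")) {
      p <- lm$par
      rss_lm <- sum(resid_fun(p)^2)
      if (is.finite(rss_lm) && rss_lm <= res$residual_norm^2) {
        res$v_bw <- p[1]; res$D <- p[2]; res$D_star <- p[2] + p[3]
        res$flow <- res$v_bw * res$D_star
        res$residual_norm <- sqrt(rss_lm)
        res$n_iter <- res$n_iter + lm$niter
      }
    }
  }
  structure(list(
    params = list(v_bw = res$v_bw, D = res$D, D_star = res$D_star,
                  flow = res$flow),
    residual_norm = res$residual_norm,
    segmented_residual_norm = res$segmented_residual_norm,
    converged = res$converged, method = method, n_iter = res$n_iter,
    dstar_unidentifiable = res$v_bw < 0.005), class = "fit_result")
}

#' Fit the IVIM model voxel-wise over a volume
#'
#' Applies the (vectorized) per-voxel estimator across the brain mask of a
#' normalized DWI series and assembles the four parameter maps compared in
#' group analyses. Voxels whose fit is invalid (too few positive points, no
#' usable tail) are removed from the validity mask and set to NA in all maps.
#'
#' @param dwi Normalized 4D `dwi_series` (b = 0 entry equal to 1 in mask).
#' @param method `"segmented"` (default) or `"full_nls"`.
#' @param options See [ivim_fit_options()].
#' @return An `ivim_maps` object: 3D arrays `v_bw`, `D`, `D_star`, `flow`,
#'   logical `mask`, plus `voxel_size_mm`, `method` and fit diagnostics.
#' @export
fit_ivim_volume <- function(dwi, method = c("segmented", "full_nls"),
                            options = ivim_fit_options()) {
  method <- match.arg(method)
  stopifnot(inherits(dwi, "dwi_series"))
  if (!isTRUE(dwi$normalized))
    stop("fit_ivim_volume expects a normalized series (see normalize_to_b0)")
  d <- dim(dwi$signal)
  mask <- dwi$brain_mask
  if (!any(mask)) stop("empty brain mask")
  mv <- which(mask)
  Y <- matrix(dwi$signal, ncol = d[4])[mv, , drop = FALSE]
  res <- fit_ivim_matrix(Y, dwi$b_schedule, method, options)
  out_mask <- array(FALSE, dim = d[1:3])
  out_mask[mv[res$valid]] <- TRUE
  mk_map <- function(vals) {
    m <- array(NA_real_, dim = d[1:3])
    m[mv] <- vals
    m[!out_mask] <- NA_real_
    m
  }
  structure(list(
    v_bw = mk_map(res$v_bw), D = mk_map(res$D), D_star = mk_map(res$D_star),
    flow = mk_map(res$flow), mask = out_mask,
    residual_norm = mk_map(res$residual_norm),
    voxel_size_mm = dwi$voxel_size_mm, method = method, options = options,
    n_invalid = sum(!res$valid)), class = "ivim_maps")
}
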