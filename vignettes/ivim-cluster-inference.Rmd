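---
title: "IVIM parameter mapping and cluster-level group inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{IVIM parameter mapping and cluster-level group inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Diffusion-weighted MRI signal in brain tissue decays with diffusion
weighting $b$ through two mechanisms: genuine water diffusion in
parenchyma, and pseudo-diffusion of blood water moving through randomly
oriented capillaries. The intravoxel incoherent motion (IVIM) model
describes the fractional signal as a two-compartment mixture,

$$\frac{S(b)}{S_0} \;=\; (1 - v_{bw})\, e^{-bD} \;+\; v_{bw}\,
e^{-b\,(D + D^{*})},$$

with $v_{bw}$ the blood-water fraction, $D$ (mm²/s) the parenchymal
diffusion coefficient and $D^{*}$ (mm²/s) the pseudo-diffusion coefficient
of the microvascular compartment. The derived product $D^{*} \times v_{bw}$
indexes microvascular blood flow. Because the perfusion compartment decays
one to two orders of magnitude faster than the tissue compartment, low $b$
values ($\lesssim 200$ s/mm²) carry the perfusion information and high $b$
values determine $D$.

A convention note: the fast-compartment rate is written here as $D + D^{*}$.
Part of the IVIM literature uses $D^{*}$ alone as the fast rate. Both are
available (`fast_rate = "sum"` is the default; `"dstar_only"` is the
alternative); fitted $D^{*}$ differs between the conventions by exactly $D$,
so results are trivially convertible.

## Estimation

`fit_ivim_voxel()` / `fit_ivim_volume()` implement two estimators:

* **Segmented** (default): $D$ comes from an ordinary log-linear fit of the
  $b \ge b_{cut}$ tail ($b_{cut} = 200$ s/mm² by default; with
  $D^{*} \ge 10\times10^{-3}$ mm²/s the perfusion term has decayed by at
  least $e^{-2}$ there, and the residual contamination biases $D$ upward by
  under 2 %). With $D$ fixed, $v_{bw}$ and $D^{*}$ are then estimated by
  bounded least squares on the full curve — a profiled grid search over
  $D^{*}$ candidates (where the optimal $v_{bw}$ is a clamped linear
  solution) followed by damped Gauss–Newton refinement.
* **Full** (`full_nls`): simultaneous bounded least squares over all three
  parameters, initialized at the segmented solution (bound midpoints if the
  segmented step fails) and accepted only if it does not increase the
  residual, so the full fit is never worse than its start.

Box constraints are $v_{bw} \in [0, 0.3]$, $D \in [0, 3\times10^{-3}]$,
$D^{*} \in [D, 0.1]$ mm²/s — physiological brain ranges whose main role is
to prevent compartment swapping. The constraint $D^{*} \ge D$ makes the
vascular compartment the faster one by construction. Convergence uses a
residual-sum-of-squares tolerance of $10^{-10}$ with at most 200 iterations
per voxel. Voxels with an estimated $v_{bw} < 0.005$ carry no usable
information on $D^{*}$; they are flagged `dstar_unidentifiable` rather than
excluded. On noiseless curves the full fit recovers parameters to better
than $10^{-6}$ relative error across the bound box; under noise, $D$ is the
best-determined parameter, $v_{bw}$ is noisier, and $D^{*}$ is by far the
noisiest — a well-known property of the model, which is why group maps of
$D^{*}$ should be read with more caution than those of $D$.

## Preprocessing

The raw acquisition has one magnitude volume per $b$ value and gradient
direction. The fixed processing order is: average the gradient directions
per $b$ value, smooth each volume with a Gaussian kernel (default FWHM
8 mm, converted per axis to voxel units so anisotropic voxels get an
isotropically sized physical kernel), then divide by the $b = 0$ volume to
obtain fractional signal. Convolution uses nearest-neighbour replication at
the boundary, which avoids edge darkening; rows of the kernel matrix sum to
one, so constants are preserved and non-negative inputs stay non-negative.
An alternative path that fits unsmoothed series and smooths the parameter
maps instead is available (`smooth_target = "maps"`) for sensitivity
analyses. Voxels whose $b=0$ signal is not positive are dropped from the
mask rather than aborting the volume.

## Group inference

Parameter maps are compared between cohorts with a pooled-variance
two-sample $t$ test per voxel ($\nu = n_A + n_B - 2$), both one-sided
contrasts run at the same nominal cluster-forming threshold (thresholds are
user-supplied inputs; nothing in the package searches for them).
Supra-threshold voxels are grouped into connected components under
18-neighbour connectivity by default (6 and 26 are selectable), labelled
deterministically in raster order of each component's first voxel.

Cluster-level family-wise-error-corrected $p$ values come from either of
two routes:

* **Random field theory.** The $t$ threshold is converted to an
  equi-probable Gaussian threshold $u$, and Gaussian-field results are used
  from there — the simplest defensible choice at $\nu \approx 20$, with the
  permutation route available as the exact reference. The expected cluster
  count is $E[m] = R\,\rho_3(u)$ with $R$ the resel count and
  $\rho_3(u) = (4\ln 2)^{3/2}(2\pi)^{-2}(u^2-1)e^{-u^2/2}$; extent follows
  $P(n \ge k) = \exp(-\beta k^{2/3})$ with $\beta$ matched to the expected
  cluster size; and the corrected $p$ is the Poisson-clumping probability
  $1 - \exp(-E[m]\,P(n \ge k))$. Smoothness is estimated from the
  standardized residuals of the two-group model (not the raw maps): the
  per-axis variance of lattice first differences is inverted through the
  Gaussian autocorrelation model $\rho(h) = e^{-h^2\lambda/2}$, i.e.
  $\lambda = -2\log(1 - \widehat{E}[\Delta^2]/2)$, rather than the small-$h$
  quadratic approximation — at FWHM below about three voxels the raw
  difference variance underestimates $\lambda$ appreciably, and the exact
  inversion removes that bias. Forming thresholds below $t = 1.5$ attach a
  warning: extent theory is unreliable there.
* **Permutation.** Group labels are permuted (exhaustively when the number
  of arrangements is small, at most `exhaustive_cap`), the maximum cluster
  size forms the null, and $p = (1 + \#\{M_{null} \ge k\})/(1 + n_{perm})$
  (plain proportion including the identity when exhaustive). This is the
  assumption-free reference against which the analytic route is calibrated.

On null simulations with smooth Gaussian fields at the default geometry the
analytic route's family-wise false-positive rate at $p < 0.05$ sits near
0.04 and the permutation route near 0.05 — both computed in the test suite,
not asserted from theory. RFT remains approximate on desk-scale grids; when
in doubt, use `correction = "perm"`.

Significant cluster masks from the four parameter maps can be intersected
(`intersect_significant_clusters()`) to define the region where all IVIM
parameters are jointly affected; that region then feeds the association
stage.

## The phantom

No imaging data ship with the package; the phantom module generates
complete two-group cohorts with known ground truth so that every downstream
claim is testable. Per subject, each true parameter field is a regional
mean (baseline, plus the effect shift inside the effect region for the
patient group) plus a subject-level random offset plus a smooth Gaussian
random field (white noise convolved to a 12 mm FWHM and exactly
variance-normalized), clamped to the physical bounds. The effect region is
an ellipsoid in the posterior third of the grid — posterior cluster
geometry without anatomy. The forward signal is the IVIM equation; noise is
Rician (the magnitude of the complex Gaussian-perturbed signal, SD
$\sigma S_0$ per channel), drawn independently per gradient direction;
additive Gaussian noise is available for oracle tests. No cerebrospinal
fluid compartment is modelled (the emulated acquisition suppresses CSF),
and there is no motion, eddy-current or registration error — cohorts are
born aligned, so tests exercise the analysis, not spatial normalization.

Default study conditions: 11 subjects per group on a 24 × 24 × 12 grid of
3.75 × 3.75 × 5 mm voxels, the 15-point schedule
$b = 0, 5, 10, 20, 30, 40, 60, 80, 120, 160, 200, 300, 500, 750, 1000$
s/mm², three gradient directions, noise $\sigma = 0.02\,S_0$. The grid is
deliberately small — desk-scale runtime with intact 3D cluster topology.
Healthy-tissue baselines ($v_{bw} = 0.05$, $D = 0.8\times10^{-3}$,
$D^{*} = 10\times10^{-3}$ mm²/s) are literature-typical brain values, not
fitted to any dataset. Patient-group shifts (lower $v_{bw}$, higher $D$,
$D^{*}$ and flow product: $-0.015$, $+0.35\times10^{-3}$,
$+14\times10^{-3}$ mm²/s) and the variance split between subject offsets
and spatial fields were fixed by a design-stage power analysis: with the
measured per-voxel between-subject spreads (which include fitting noise)
they give voxel-level effect sizes $d \approx 3$ for the weakest contrasts
($v_{bw}$ and the flow product — the latter is structurally the weakest
because the $v_{bw}$ decrease and $D^{*}$ increase partially cancel in
their product) and stronger ones for $D$ and $D^{*}$, so that a correctly
implemented pipeline detects all four effects reliably at $n = 11$ while a
mis-calibrated one does not. The effect ellipsoid spans roughly 580 voxels,
comparable in scale to the posterior clusters such a study reports.
Covariates are linear in the true regional mean of a named parameter plus
Gaussian noise; the defaults couple two cognitive-style scores negatively
to regional flow, a disease-activity-style score negatively to $v_{bw}$,
and include a zero-slope null covariate for calibration.

What passing tests on this phantom do **not** show: robustness to motion or
misregistration, anatomical heterogeneity, CSF partial-volume effects, or
non-stationary smoothness — all absent from the generator by design.

## Associations

Within a region fixed by the inference stage (the pipeline enforces that
the region is defined before covariates are seen), the per-subject regional
median of each parameter is correlated with each covariate: Pearson $r$
(Spearman optional; the linear regression line is reported alongside, which
is why Pearson is the default), two-sided $p$ from the $t$ transform with
$n - 2$ degrees of freedom, patients only by default. Unadjusted $p$ values
are primary — mirroring the exploratory, small-sample design the package
emulates — flagged at $p < 0.05$ and $p < 0.1$; a Benjamini–Hochberg
column is always emitted for modern practice. Missing covariate values are
dropped pairwise with a recorded count.

## Numerical and design notes

* All randomness is seeded; a cohort is byte-reproducible from its spec.
  Derived seeds stay within 32-bit integer range.
* Cluster labelling, the only hot combinatorial path, is compiled (C++);
  everything else is vectorized R.
* The permutation null recomputes $t$ maps by matrix algebra across
  arrangements; with 199 permutations the minimum attainable $p$ is 0.005,
  ample for tests at $\alpha = 0.05$.
* Even-sized regional medians average the central pair (the standard sample
  median).
* Voxel coordinates are 0-based internally; mm coordinates are produced
  only at reporting boundaries through the stored affine (diagonal, origin
  at the grid centre — synthetic grids have no standard-space meaning).
* Degenerate inputs are contained, not fatal: non-positive $b=0$ voxels
  leave the mask, non-converged fits are flagged and excluded from maps,
  zero-variance voxels leave the $t$-map mask, and zero-variance
  correlation inputs raise an explicit error.
* Test and simulation problem sizes (500 null simulations for FWE
  calibration, 20 cohort replicates for end-to-end recovery, 100 for
  association power, 200 voxels per noisy-calibration point) were chosen to
  bound Monte-Carlo error well inside the asserted tolerance bands at
  desk-scale runtime.

## Known limitations

* RFT cluster inference is approximate at low smoothness and small search
  volumes; the permutation route is the reference when they disagree.
* The Gaussian-field (rather than $t$-field) extent formula with the
  equi-probable threshold conversion is a simplification; at
  $\nu \approx 20$ its miscalibration is absorbed by the documented
  tolerance, and it is conservative rather than liberal in our null
  simulations.
* $D^{*}$ estimates are intrinsically noisy at $v_{bw} \approx 0.05$; no
  hard accuracy bound is claimed for them.
* No Bayesian or spatially regularized fitting, no tri-exponential or
  kurtosis extensions, no direction-resolved (tensor) modelling, no
  covariate-adjusted group models, and no TFCE or peak/set-level inference.
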