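# ivimtools

Intravoxel incoherent motion (IVIM) parameter mapping and cluster-level
group inference for multi-b-value diffusion MRI.

Cerebral microvascular compromise — reduced capillary blood volume, altered
perfusion — is hard to measure non-invasively, yet it is implicated in the
cognitive symptoms of systemic inflammatory disease. IVIM imaging separates
the diffusion-weighted signal of a voxel into a tissue-water compartment and
a blood-water compartment from a single multi-b acquisition, with no
contrast agent. `ivimtools` is for researchers running small two-cohort
IVIM studies of the brain: it fits the IVIM model voxel-wise, localizes
group differences with cluster-level family-wise-error-corrected inference,
and correlates regional parameter medians with clinical covariates. Because
such studies rarely share raw MRI, the package also ships a synthetic
phantom module that generates complete two-group cohorts with known ground
truth, so the entire pipeline is testable end to end on any machine.

## The model

The fractional signal at diffusion weighting `b` (s/mm²) is

    S(b)/S0 = (1 - v_bw) exp(-b D) + v_bw exp(-b (D + D*))

where `v_bw` is the blood-water fraction, `D` (mm²/s) the parenchymal
diffusion coefficient, and `D*` (mm²/s) the pseudo-diffusion coefficient of
microvascular water. The product `D* × v_bw` indexes blood flow. Fitting is
segmented (log-linear high-b tail for `D`, then bounded least squares for
`v_bw` and `D*`) or full nonlinear least squares started from the segmented
solution. Group inference is a voxel-wise pooled two-sample t test, cluster
formation at a nominal T threshold, and cluster-level corrected p values by
Gaussian random field theory (smoothness estimated from standardized
residuals) or by permutation of group labels.

## Worked example

```r
library(ivimtools)

# a single voxel: forward signal on the 15-point schedule, then recovery
b <- phantom_spec()$b_schedule
y <- ivim_signal(v_bw = 0.05, D = 0.8e-3, D_star = 10e-3, b)
fit <- fit_ivim_voxel(y, b, method = "full_nls")
unlist(fit$params)
#>     v_bw        D   D_star     flow
#> 5.0e-02  8.0e-04  1.0e-02  5.0e-04

# a full synthetic study: 11 patients vs 11 controls, posterior effect
res <- run_pipeline(list(seed = 11L), out_dir = tempfile("ivim_run_"))
subset(res$clusters, significant,
       select = c(parameter, contrast, size_voxels, p_fwe))
#>     parameter        contrast size_voxels        p_fwe
#> 10       v_bw patient<control         523 3.832271e-07
#> 47          D patient>control         833 7.048117e-04
#> 48          D patient<control         627 3.234403e-03
#> 65     D_star patient>control         730 7.327472e-15
#> 139      flow patient>control         618 4.793376e-10
sum(res$intersection)        # voxels where all four parameters differ
#> [1] 443
subset(res$associations, parameter == "flow" & covariate == "vca_z",
       select = c(parameter, covariate, n, r, p))
#>    parameter covariate  n          r            p
#> 13      flow     vca_z 11 -0.9250014 4.548324e-05
```

The cluster table mirrors the usual neuroimaging report: one row per
supra-threshold cluster with its peak location (mm), forming threshold,
extent in voxels and corrected p value. Patients were simulated with lower
`v_bw` and higher `D`, `D*` and flow in a posterior ellipsoid, and the
pipeline recovers exactly that pattern; the association table shows the
planted negative coupling between regional flow and the
visuoconstructional-style covariate. The `D patient<control` row is
instructive: it lies entirely outside the planted region and is driven by
a chance alignment of smooth between-subject variation — at n = 11 per
group such opposite-direction clusters can reach corrected significance,
which is precisely why small-sample cluster findings warrant replication.

A thin command-line wrapper for shell use is in `inst/cli/ivim.R`
(`simulate`, `fit`, `compare`, `associate`, `run-all`).

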