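---
title: "Multiparametric features of metabolism from hyperpolarized 13C MRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiparametric features of metabolism from hyperpolarized 13C MRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hpmfm)
```

# Overview

Hyperpolarized (HP) [1-^13^C]pyruvate MRI measures the Warburg effect in
vivo: injected pyruvate is converted to lactate by LDH at an apparent rate
k~PL~, and the dynamic ^13^C signal lets that rate be mapped voxel by
voxel. `hpmfm` implements a complete analysis chain for such data in
advanced prostate cancer-style cohorts:

1. **Kinetic maps** — voxelwise k~PL~ (inputless two-site exchange),
   pyruvate signal summed over time (AUC), and mean pyruvate time (MT,
   the bolus center of mass), resampled to a 5 mm isotropic analysis grid.
2. **Feature bank** — fixed-bin-width discretization and first-order,
   shape, and gray-level texture features (GLDM, GLRLM, GLSZM) over the
   pooled lesion ROI, plus the total metabolic volume (TMV).
3. **Survival machinery** — Cox proportional-hazards fits with
   likelihood-ratio tests, Harrell's concordance index, Kaplan–Meier
   curves with "median not reached" handling, and median imputation of
   missing ALP serology.
4. **Metabolic Prognostic Score (MPS)** — concordance-ranked, top-20%
   retained, correlation-clustered feature selection, an age-adjusted
   multivariate Cox score with median dichotomization, and leave-one-out
   coefficient-stability assessment.
5. **Synthetic cohort generator** — the package's test bed: dynamic
   series, lesion masks and linked survival tables with a known
   generative law, so every downstream stage can be validated without any
   patient data.

# The two-site exchange model

## Forward simulation

The simulator propagates pyruvate (P) and lactate (L) longitudinal
magnetization at the frame times $t_i = i \cdot TR$ (default TR = 3 s, 20
frames, flip angles 15°/30° for pyruvate/lactate):

$$P_{i+1} = P_i \cos\theta_P \, e^{-TR \cdot r_{1P}} + U_i$$
$$L_{i+1} = L_i \cos\theta_L \, e^{-TR \cdot r_{1L}} +
  k_{PL} \, TR \, \tfrac{1}{2}\left(P_i \cos\theta_P + P_{i+1}\right)$$

with signals $S_X = M_X \sin\theta_X$ plus additive Gaussian magnitude
noise. $U_i$ is the gamma-variate bolus $u(t) = A\,t^{\alpha}
e^{-t/\beta}$ integrated over the frame interval (closed form via the
incomplete gamma function). The bolus form is a simulator choice — the
fitter never sees it — and defaults ($\alpha = 2.5$, $\beta = 4.5$ s,
peak around 11 s) give realistic bolus shapes. Relaxation rates default to
$r_{1P} = r_{1L} = 1/25\ \mathrm{s}^{-1}$, typical published effective
values at 3 T. The bolus amplitude default (0.002) sets the in-lesion AUC
scale to order one so that the fixed AUC bin width (below) yields on the
order of 100 gray levels, the regime the method was designed around.

A `substeps` argument integrates the continuous-time exchange ODE on a
finer grid between excitations. This separates model error from estimator
error: with `substeps = 1` the simulator and fitter share one recursion
and noiseless recovery is exact to machine precision; with larger values
the recovery error measures discretization bias alone.

## Inputless fitting

The fitter (`fit_kpl_inputless`) avoids an arterial input function by
using the *measured* pyruvate signal as the source term: signals are
converted to magnetizations (divide by $\sin\theta$), the predicted
lactate is seeded from the first measured lactate frame and propagated
with the same recursion (lactate T1 fixed at 25 s, not fitted — the
established convention that keeps the fit one-dimensional per voxel), and
$k_{PL} \ge 0$ minimizes the sum of squared lactate-signal residuals.
Because the predicted lactate is exactly linear in $k_{PL}$ given the
measured pyruvate, the bounded minimizer has a closed form (a projection
clamped to the bounds); an iterative bounded search is retained internally
as a cross-check and agrees to the solver tolerance. k~PL~ is reported in
ks^-1^ (10^-3^ s^-1^), the field's reporting unit.

**Noise floor.** Voxels whose pyruvate peak does not exceed 3× the robust
noise scale are zero-filled (and MT is likewise guarded against
division by near-zero signal sums). The noise scale is the MAD of the
first dynamic frame, which precedes bolus arrival and so carries noise
only; centering the MAD on the median makes the floor vanish exactly for
noise-free input. Whether sub-floor voxels should instead be excluded
from the ROI entirely is genuinely open; zero-filling was chosen and is
flagged for sensitivity analysis.

## Resampling

All three maps are resampled to a 5 mm isotropic axis-aligned grid
covering the native field of view — trilinear interpolation for
intensities, nearest-neighbour for the integer lesion-label mask. The
interpolator dialect is a documented choice; constants are preserved
exactly and world-space lesion centroids move by less than half a native
voxel (both are tested).

# The feature bank

Features are computed over the *composite* patient ROI: all lesion labels
pooled, restricted to voxels with measurable pyruvate signal. Pooling is
supported by the way median k~PL~ is defined across ROIs; a per-lesion
mode with volume weighting would be equally defensible and the pooled
default was chosen for simplicity and testability.

* **Discretization** uses a fixed bin width anchored at the ROI minimum
  (`level = floor((x - min)/w) + 1`, maximum clamped into the top bin).
  Fixed width, not fixed count, follows the quantitative-imaging
  literature on reproducibility. Defaults: 1 ks^-1^ for k~PL~, 0.02
  signal units for AUC, 0.1 s for MT. Note the k~PL~ width is the same
  physical width often quoted as 0.001 in s^-1^ units.
* **First-order** (18 features) includes mean, median, variance,
  skewness, non-excess kurtosis (a normal distribution scores 3; for the
  degenerate constant ROI the limits skewness = 0, kurtosis = 3 are
  used), energy and volume-weighted total energy, histogram entropy and
  uniformity (on the discretized values), extrema, percentiles (type-7
  quantiles), IQR, mean absolute deviation, its robust (10–90 percentile)
  variant, and RMS.
* **Shape elongation** is $\sqrt{\lambda_2 / \lambda_1}$ of the ROI
  coordinate covariance — the square-root aspect ratio of the two largest
  principal axes; a single-voxel ROI is reported missing.
* **Texture**: GLRLM counts maximal equal-level runs along the 13 unique
  3-D directions and sums the per-direction matrices before scalar
  computation (one of the two standard aggregation dialects, fixed here
  for reproducibility; run percentage is normalised by voxels ×
  directions accordingly). GLSZM counts 26-connected equal-level zones by
  size. GLDM uses the dependence count 1 + (number of equal-level
  26-neighbours), so the dependence index starts at 1 and the
  small-dependence denominators are always defined. The scalar sets (16,
  16, 14 features) follow the standardized formulas. The builders are
  compiled (Rcpp) and are verified feature-by-feature against brute-force
  enumerators on random volumes.
* **TMV** is the volume (mL) of in-mask voxels with positive k~PL~.

Names follow `<map>_original_<class>_<Feature>` with map prefixes `kPL`,
`pyrAUC`, `MT`, plus `TMV` — 196 features in total per patient (65 per
map + TMV). The historical figure of ~316 features depends on a feature
class composition that is not recoverable; the documented name set here
is the contract, and shape features are emitted per map with identical
values (matching the per-map naming convention of composite scores such
as `pyrAUC_original_shape_Elongation`).

# Survival machinery

`cox_fit` wraps the partial-likelihood maximisation of the `survival`
package (Breslow tie handling — ties are rare in continuous simulated
time, and the convention is documented so results are reproducible across
implementations) and reports the coefficient vector, inverse-information
covariance, the likelihood-ratio test against the null model, Harrell's C
of the fitted linear predictor, and Wald 95% hazard-ratio intervals.
Monotone-likelihood divergence is detected, capped and flagged.

`harrell_c` is implemented in-package with the exact pair rules used
throughout: a pair is usable iff the smaller observed time is an observed
event; tied risks count 1/2; tied times are unusable. It is checked
against quadratic brute-force enumeration.

`km_curve` reports the product-limit estimate with the median defined as
the smallest time at which the curve reaches 0.5 or below, and "NR" (not
reached) as a distinguished outcome. `km_by_group` dichotomizes a score
at a threshold (low group: score ≤ threshold) and reports per-group
medians plus the Cox LRT p of the group indicator. The package reports
the Cox likelihood-ratio p for group comparisons — the same machinery
used everywhere else — rather than a log-rank statistic.

Missing ALP values are completed with the cohort median of the observed
readings before any model sees them.

# The MPS chain

1. **Ranking.** Each candidate feature (all imaging features plus PSA,
   LDH, ALP) is scored by the adjusted C-index $0.8\,C_{PFS} +
   0.2\,C_{OS}$, each C being Harrell's C of a univariate Cox fit's
   linear predictor. The Cox-fit C self-orients (the coefficient sign
   adapts), consistent with retained scores living above 0.5. The PFS
   weighting reflects the endpoint's greater maturity. The top
   `ceiling(0.2 × n)` features are retained; ties break by name so the
   ranking is deterministic. (No simple rounding rule reproduces the
   historical 65-of-319 count exactly; the ceiling rule is fixed and the
   discrepancy recorded.)
2. **Clustering.** Pairwise distance $1 - |r|$ (absolute Pearson
   correlation) feeds average-linkage agglomerative clustering — the
   standard default for correlation-distance dendrograms — cut into 4
   branches. From each branch the member with the highest adjusted
   C-index is selected; the cluster-ordered correlation matrix is emitted
   for correlogram rendering.
3. **Score.** A multivariate Cox model of the representatives *plus
   patient age as a covariate* (age adjustment by covariate, not
   stratification) is fitted on the PFS endpoint; OS metrics are reported
   from the same score. The MPS is the pure linear combination
   $\sum_i \beta_i x_i$ — lower is favorable — and patients are
   dichotomized at the cohort-median MPS. Collinear representatives
   trigger a condition-number warning and a ridge-stabilised refit.
4. **Stability.** Each patient is withheld in turn and the model refitted;
   the per-coefficient standard deviation across the n refits, divided by
   the absolute full-cohort coefficient, is the normalized SD. A refit
   set with zero spread reports 0 by convention even for a zero full
   coefficient.

The correlogram correlates features and serology with *observed* PFS/OS
durations, censored durations entering as observed follow-up — a
documented approximation, adequate for the visualization it feeds.

# The synthetic cohort generator

The generator emulates the data structure the analysis assumes: 16
patients by default, 1–4 ellipsoidal lesions each (site labels drawn with
bone-dominant frequencies), lesion k~PL~ around a 17 ks^-1^ clinical
cutoff (patient-level lognormal, median 15 ks^-1^, with lesion- and
voxel-level lognormal heterogeneity), voxelwise perfusion (bolus
amplitude) variation and per-lesion bolus delays so the MT map is
informative, and complex-noise-regime additive Gaussian signal noise
(default peak-pyruvate SNR ≈ 30, where Rician bias is negligible).
Serology and age distributions match published cohort summaries (age
69 ± 10; PSA median 13.9, LDH 208, ALP 76); two ALP values are blanked by
default to exercise the imputation path.

Survival is generated from a Weibull-baseline proportional-hazards law
(inverse-transform sampling; shape 1.2, progression scale 18 months,
death scale 36 months, PFS = min(progression, death)) whose linear
predictor applies the user's `hazard_coefficients` to *standardized
generator-side truth* (true median/max/mean k~PL~, TMV, serology).
Censoring is independent uniform over a 36-month follow-up at the
requested rate. Scan-timing/treatment confounding is deliberately not
modelled.

**What passing tests do and do not show.** The generator shares its
recursion with the fitter, so noiseless round-trip exactness validates
the estimator, not the physiological model; partial-volume dilution at
lesion edges is present (maps are resampled from coarse native grids),
but B0/B1 inhomogeneity, coil sensitivity, EPI artifacts and
treatment-time confounding are not. Statistical conclusions about the
selection chain therefore transfer to real data only to the extent that
measured features track underlying biology as cleanly as they track the
generator truth here (measured vs. true median k~PL~ correlate at
r ≈ 0.98 in the default regime).

# Numerical choices and problem sizes

* Closed-form per-voxel k~PL~ least squares (exact minimizer); solver
  tolerance 1e-10 applies to the iterative cross-check path.
* Cox convergence: partial-likelihood tolerance 1e-10, up to 100
  iterations; LRT statistics are clipped at 0.
* Deterministic tie-breaks throughout (feature name in ranking and
  representative selection); fixed seeds make the whole pipeline
  byte-reproducible, which the test suite asserts on CSV outputs.
* Degenerate inputs: constant features are excluded from ranking;
  empty dichotomization groups, all-censored C-indices and single-voxel
  shape ROIs are reported as missing rather than guessed.
* Validation problem sizes were chosen to keep the full suite fast while
  leaving no statistical check underpowered: kinetic recovery on a
  3-point rate grid plus 100 noisy replicates; texture oracles on 50
  random 6×6×6 volumes; concordance oracles on 100 censored datasets
  (n = 100); Cox null calibration on 200 datasets (n = 50) and hazard
  recovery at n = 500; selection recovery on twenty 100-patient cohorts
  simulated on a compact 10×10×8 native grid.

# Worked example

```{r example, eval = FALSE}
co <- generate_cohort(cohort_spec(n_patients = 16, seed = 1))
features <- extract_cohort_features(co)
mod <- fit_mps(features, co$clinical)
print(mod)
summary(mod)

# or, end to end with artifacts on disk:
res <- run_pipeline(pipeline_config(cohort = list(n_patients = 16,
                                                  seed = 1)),
                    outdir = "hpmfm_run")
```

# Known limitations

* The inputless model fixes lactate T1 and ignores alanine/bicarbonate
  exchange and B1 miscalibration; k~PL~ is an apparent rate.
* Feature values depend on the discretization widths and the resampling
  dialect; both are fixed defaults, not fitted.
* With 16-patient cohorts the MPS coefficients are expected to be
  unstable (that is what the leave-one-out normalized SD quantifies); the
  chain is a hypothesis-generating device, not a validated classifier,
  and no train/validation split is attempted at this cohort size.
* The correlogram's use of censored durations as observed values biases
  feature-outcome correlations toward zero for heavily censored
  endpoints.
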