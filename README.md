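# hpmfm — multiparametric features of metabolism from hyperpolarized ¹³C-pyruvate MRI

Hyperpolarized [1-¹³C]pyruvate MRI images the Warburg effect directly: the
apparent pyruvate→lactate conversion rate k<sub>PL</sub> (reported in
ks⁻¹ = 10⁻³ s⁻¹) is an imaging surrogate of LDH-driven malignant
metabolism, and in advanced prostate cancer its spatial statistics carry
prognostic information. `hpmfm` is an R package for turning dynamic
¹³C series and lesion masks into that prognostic read-out, and for
validating every step of the chain on synthetic cohorts with a known
generative law.

The package implements:

* **Kinetic parametric maps** — voxelwise k<sub>PL</sub> from the
  *inputless* two-site exchange model (the measured pyruvate signal is the
  source term, so no arterial input function is needed; lactate T1 fixed
  at 25 s; closed-form bounded least squares per voxel), pyruvate
  summed-over-time (AUC), and mean pyruvate time
  (MT = Σtᵢ·S(i) / ΣS(i), the bolus center of mass), resampled to a 5 mm
  isotropic analysis grid.
* **A radiomic-style feature bank** — fixed-bin-width discretization;
  18 first-order features; PCA shape elongation √(λ₂/λ₁); GLDM, GLRLM and
  GLSZM texture matrices (compiled, oracle-verified) with their 14/16/16
  standardized scalar features; total metabolic volume (TMV). 196 named
  features per patient, `<map>_original_<class>_<Feature>`.
* **Survival machinery** — Cox proportional hazards (Breslow ties) with
  likelihood-ratio tests, Harrell's concordance index with exact pair
  rules, Kaplan–Meier curves with "NR" median handling, median ALP
  imputation.
* **The Metabolic Prognostic Score (MPS)** — features ranked by the
  adjusted C-index 0.8·C<sub>PFS</sub> + 0.2·C<sub>OS</sub>, top 20%
  retained, clustered by the distance 1 − |Pearson r| (average linkage, 4
  branches), one representative per cluster, then an age-adjusted
  multivariate Cox score MPS = Σβᵢxᵢ dichotomized at the cohort median,
  with leave-one-out coefficient stability.
* **A synthetic cohort generator** — dynamic series, lesion label masks
  and clinical tables whose PFS/OS arise from a Weibull-baseline
  proportional-hazards law on true (generator-side) imaging features, with
  right censoring. Identical seeds give byte-identical cohorts.

## Worked example

```r
library(hpmfm)

co <- generate_cohort(cohort_spec(n_patients = 16, seed = 1))
co
#> Synthetic HP 13C cohort: 16 patients, 35 lesions
#>   native grid 16x16x12 voxels @ 20x20x20 mm, 20 frames, TR 3 s
#>   PFS events: 12  OS events: 8

features <- extract_cohort_features(co)   # 16 x 197 (patient_id + features)
mod <- fit_mps(features, co$clinical)
mod
#> Metabolic Prognostic Score model (Cox PH, PFS endpoint)
#> Selected variables: kPL_original_firstorder_Median,
#>   kPL_original_gldm_GrayLevelNonUniformity,
#>   kPL_original_glszm_LargeAreaLowGrayLevelEmphasis,
#>   MT_original_glszm_GrayLevelVariance
#> MPS = 0.3177 x kPL_original_firstorder_Median + 0.02371 x
#>   kPL_original_gldm_GrayLevelNonUniformity + -0.1012 x
#>   kPL_original_glszm_LargeAreaLowGrayLevelEmphasis + -0.00324 x
#>   MT_original_glszm_GrayLevelVariance + -0.01971 x Age
#> Dichotomization threshold (cohort median MPS): -9.062
#> PFS: LRT p = 0.000191, C-index = 0.873 | OS: LRT p = 0.0005, C-index = 0.885

mod$km_pfs
#> Dichotomized Kaplan-Meier: median 27.125 (low, n = 8 ) vs 5.46 (high, n = 8 )
#> LRT p = 0.00233  group C-index = 0.75
```

The cohort's hazard is driven (by default) by true median k<sub>PL</sub>,
and the chain recovers that: the median-k<sub>PL</sub> feature is selected
with a positive coefficient, the low-MPS half of the cohort lives without
progression about five times longer than the high-MPS half, and the score
concordance (C-index 0.87 for PFS) summarizes how often the higher-risk
patient of a comparable pair progresses first. The leave-one-out
normalized coefficient SDs in `mod$loo_normalized_sd` (0.14–0.35 for the
imaging terms here) quantify how fragile those coefficients are at n = 16.

The same chain runs end to end with artifacts on disk (NIfTI maps, CSV
tables, JSON reports):

```r
run_pipeline(pipeline_config(cohort = list(n_patients = 16, seed = 1)),
             outdir = "hpmfm_run")
```

or from a shell via the staged CLI
(`Rscript inst/cli/hpmfm.R run-all --out hpmfm_run --seed 1`).

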