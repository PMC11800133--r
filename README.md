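# glymphalps

Glymphatic-function analysis of diffusion MRI via the DTI-ALPS index, with a
synthetic phantom and cohort simulator so the whole pipeline is testable
without patient data.

## Scientific background

The glymphatic system clears metabolic waste from the brain through
perivascular spaces. *Diffusion tensor image analysis along the perivascular
space* (DTI-ALPS) probes it noninvasively: at the level of the lateral
ventricle body, the deep medullary veins run left-right (x), perpendicular to
the projection fibers (principal diffusion axis inferior-superior, z) and the
association fibers (principal axis anterior-posterior, y). Diffusivity along
x in these tracts is therefore attributable to the perivascular channel, and
the index

```
ALPS = (Dx_proj + Dx_assoc) / (Dy_proj + Dz_assoc)
```

compares it against the tracts' non-dominant axes. Values near 1 mean no
preferential perivascular diffusion; healthy adults typically measure around
1.4-1.5. In acute spontaneous intracerebral hemorrhage (sICH) the index drops
on the side of the hematoma, tracks hemorrhage and perihematomal edema
volumes, and predicts 90-day functional outcome (modified Rankin Scale <= 2).

The package implements, in plain R:

* **Synthetic DWI phantom** (`phantom_spec()`, `build_alps_phantom()`):
  periventricular geometry with known ground-truth tensors, a 30-direction
  b = 1000 s/mm^2 scheme, Rician noise, and nested hematoma/edema lesions.
* **Diffusion tensor estimation** (`fit_tensor()`): log-linear least squares
  (WLS variant available), plus eigendecomposition, fractional anisotropy,
  direction-encoded color FA and the Dxx/Dyy/Dzz axis-diffusivity maps.
* **ALPS computation** (`extract_roi_means()`, `compute_alps()`,
  `lateralize()`): 5 mm ROI discs on the deep-medullary-vein slice,
  hemispheric indices, ipsilateral/contralateral labelling against the
  lesion side (subtentorial lesions use the two-side average).
* **Lesion volumetry** (`mask_volume()`, `edema_volume()`,
  `relative_edema_ratio()`): hematoma and total-lesion masks on their native
  grids; edema by scalar subtraction; the edema/hemorrhage quotient.
* **Cohort simulator** (`cohort_params()`, `simulate_cohort()`): Gaussian
  copula over ALPS indices, volumes, age, NIHSS and disease duration, with
  marginals and associations calibrated to published summary statistics and
  a logistic 90-day outcome model.
* **Statistics** (`ttest_two_sample()`, `correlation()`,
  `categorical_2x2()`, `logistic_fit()`, `linear_fit()`, `ks_normality()`,
  `covariate_screen()`): the full battery such studies report, including
  t-tests directly on published mean +/- SD summaries and odds ratios per
  0.1 increase of the ALPS index.
* **Pipeline driver** (`validate_config()`, `run_pipeline()`, and the thin
  wrapper `inst/scripts/alps-glymph.R`): YAML-configured end-to-end runs
  with per-stage seeds and a checksummed JSON manifest.

## Worked example

```r
library(glymphalps)

# phantom -> tensor fit -> ALPS
spec <- phantom_spec(grid = c(48, 48, 16), S0 = 500)
ph <- build_alps_phantom(spec)
field <- fit_tensor(ph$dwi)
maps <- axis_diffusivities(field)
tr <- ph$truth$roi_centers
rois <- mapply(function(h, f, i, j, k) roi_spec(h, f, c(i, j, k)),
               tr$hemisphere, tr$fiber_class, tr$i, tr$j, tr$k,
               SIMPLIFY = FALSE)
alps_from_maps(maps, rois, spec$voxdim, lesion_side = "left")$result
#> DTI-ALPS index
#>   left  1.4583   right 1.4583
#>   ipsilateral 1.4583   contralateral 1.4583   (lesion: left)
#>   average 1.4583
```

The noiseless pipeline recovers exactly the index implied by the phantom's
assigned fiber tensors, (1.1 + 1.0)/(0.6 + 0.84) = 1.458 — a healthy-adult
value by construction.

```r
# group comparison straight from published summaries (n, mean, SD)
ttest_two_sample(summary_group(46, 1.34, 0.24), summary_group(97, 1.46, 0.22))
#> Student's t (pooled): statistic = -2.9585, df = 141, p = 0.003627

# simulated cohort and the multivariable outcome model
co <- simulate_cohort(cohort_params(), seed = 1)
analyze_outcome_model(co)
#>                                predictor odds_ratio     ci_low  ci_high           p
#> age                                  age  0.9690915 0.92130057 1.019361 0.223681313
#> sex                                  sex  0.5195063 0.08670118 3.112839 0.473431775
#> nihss                              nihss  0.9691420 0.79866290 1.176011 0.750836142
#> hemorrhage_volume_ml hemorrhage_volume_ml 1.0472753 0.96382200 1.137955 0.275596956
#> alps_ipsilateral         alps_ipsilateral 2.3003531 1.38477382 3.821292 0.001294566
```

The ALPS row is the odds ratio of a favorable 90-day outcome per 0.1
increase of the ipsilateral index, adjusted for age, sex, baseline NIHSS and
hemorrhage volume; at a single simulated cohort of 55 patients it is
estimated with wide uncertainty around the generator's configured effect.

An end-to-end run (phantom, fit, ALPS, volumetry, cohort, statistics) with
outputs and a checksummed manifest:

```sh
Rscript inst/scripts/alps-glymph.R --config inst/extdata/demo_config.yaml --out demo_run
```

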