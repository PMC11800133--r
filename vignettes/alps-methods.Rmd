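---
title: "Methods: the DTI-ALPS pipeline and its synthetic test bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the DTI-ALPS pipeline and its synthetic test bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glymphalps)
```

## The measurement model

A diffusion-weighted acquisition measures, per voxel and gradient direction
$g_i$ (unit vector) at b-value $b_i$ (s/mm^2),

$$S_i = S_0 \exp(-b_i \, g_i^\top D \, g_i),$$

where $D$ is the symmetric positive-definite diffusion tensor (mm^2/s).
`fit_tensor()` estimates the seven parameters $(\ln S_0, D_{xx}, D_{yy},
D_{zz}, D_{xy}, D_{xz}, D_{yz})$ per voxel by least squares on
$\ln S_i$ — the classical log-linear estimator. The design matrix depends
only on the gradient scheme, so the ordinary-least-squares fit of every
voxel reduces to one matrix product; this is what makes whole-volume fits
cheap in plain R. A weighted variant (`method = "wls"`, weights equal to the
squared predicted signals) runs one reweighting pass per voxel and is the
appropriate estimator when the log transform makes the noise
heteroscedastic; the tests use an independently coded per-voxel solver as
the cross-check for both paths.

Assumptions worth stating: one tensor per voxel (no crossing fibers), no
eddy-current or motion artifacts, and magnitude (Rician) noise. Negative
estimated eigenvalues are clamped to zero for FA and color-FA rendering
only — the stored tensor keeps the raw fit, so the Dxx/Dyy/Dzz maps that
the ALPS index reads are untouched by the clamp. Signals at or below zero
are floored at `clamp_frac` (default 1e-6) times the voxel's mean b = 0
signal before the log; the count of affected voxels is kept on the result.

## The ALPS index

On the axial slice where the deep medullary veins run perpendicular to the
body of the lateral ventricle, two circular ROIs of 5 mm diameter are placed
on the direction-encoded FA map: one in the projection fibers (principal
axis z), one in the association fibers (principal axis y). With
$D^{proj}_x, D^{proj}_y$ and $D^{assoc}_x, D^{assoc}_z$ the ROI-mean axis
diffusivities,

$$\mathrm{ALPS} = \frac{D^{proj}_x + D^{assoc}_x}{D^{proj}_y + D^{assoc}_z}.$$

The numerator collects diffusivity along the perivascular (x) direction;
the denominator collects each tract's non-dominant in-plane axes, so fiber
anisotropy itself cancels to first order and the index isolates the
perivascular contribution. Both hemispheres are always measured; a left- or
right-sided lesion relabels them ipsilateral/contralateral, while
subtentorial lesions and controls use the per-subject average of the two
sides.

Design choices that the protocol leaves open, and what this package does:

* **ROI membership** is voxel-center-in-disc on a single native-grid axial
  slice, no partial-volume weighting and no interpolation — ROIs are drawn
  on 2-D color-FA images in practice, and at 1.7 mm in-plane resolution a
  5 mm disc holds 9 voxel centers.
* **ROI placement is an input** (JSON, 0-based voxel indices), mirroring
  manual placement on the color-FA image. `suggest_alps_rois()` offers
  advisory centers by scanning the slice for the most z-dominant
  (projection) and y-dominant (association) anisotropic voxels per
  hemisphere; its output is meant to be reviewed, not trusted.
* **Orientation**: all axis-labelled computation assumes canonical RAS
  axes — x left-right, y anterior-posterior, z inferior-superior. The
  phantom is built in this frame.

## Lesion volumetry

Hematomas are delineated on susceptibility-weighted images, the total
lesion on T2 — two different native grids. Volumes are therefore computed
per grid (voxel count times voxel volume) and subtracted as scalars:
edema = total − hematoma, floored at zero with a warning when cross-modality
delineations disagree. The relative edema ratio is edema/hemorrhage and is
undefined (an error) at zero hemorrhage volume.

## The synthetic phantom

`phantom_spec()` describes a digital head: a CSF ventricle body at the
center, projection-fiber slabs immediately lateral on both sides spanning
all slices, association-fiber slabs lateral to those, uniform background,
and optionally a nested hematoma/edema ellipsoid pair. Default tissue
tensors (phantom parameters, not claims about tissue): isotropic 0.7e-3
mm^2/s background, isotropic 3.0e-3 CSF, projection diag(1.1, 0.6, 1.6)e-3,
association diag(1.0, 1.6, 0.84)e-3 — chosen so the analytic index
(1.1 + 1.0)/(0.6 + 0.84) = 1.458 sits near healthy-adult values; isotropic
0.45e-3 hematoma (restricted diffusion) and 1.1e-3 vasogenic edema. The
default grid is 96 x 96 x 40 at 1.7 x 1.7 x 2 mm with one b = 0 volume and
30 weighted directions at b = 1000 s/mm^2, matching a routine DTI protocol;
the slice gap of such protocols is ignored, since a contiguous grid
simplifies volumetry and is conservative for it. Tests and the acceptance
script use a 48 x 48 x 16 grid — wide enough that a 5 mm ROI disc stays
inside its fiber slab, small enough that a fit takes well under a second.

Gradient directions come from a deterministic spherical Fibonacci lattice:
reproducible for any count and near-uniform. Very small counts can hit
symmetry accidents of the lattice that leave the tensor design
rank-deficient (six directions do); a tiny fixed index-dependent jitter is
then applied, keeping the scheme deterministic.

Noise is Rician — each signal $S$ becomes $\sqrt{(S+n_1)^2 + n_2^2}$ with
$n_1, n_2 \sim N(0, \sigma)$ — as appropriate for magnitude MR images, with
$\sigma$ configured relative to $S_0$.

What the phantom does **not** emulate: crossing fibers, partial volume at
tissue boundaries (regions are piecewise constant), susceptibility or
motion artifacts, T2/SWI contrast beyond binary masks, or anatomically
curved tracts. Passing the phantom oracle therefore demonstrates that the
estimator, ROI extraction and index arithmetic are correct, not that the
pipeline is robust to real-world confounds.

## The cohort simulator

`simulate_cohort()` draws patients and controls whose joint distribution is
calibrated to published summary statistics of acute sICH cohorts:
ipsilateral ALPS 1.34 ± 0.24, contralateral 1.48 ± 0.21, control average
1.46 ± 0.22; hemorrhage 22.1 ± 20.1 mL and edema 24.2 ± 26.2 mL; 55
patients (9 subtentorial) versus 97 controls; binary risk factors at the
published group rates.

Continuous variables use a Gaussian copula. ALPS indices and age keep
normal marginals. For the nonnegative variables the marginal family is
chosen per variable: a zero-truncated normal moment-matched to the printed
mean ± SD where that is achievable, and a moment-matched lognormal where
the printed SD is of the order of the mean (the truncated normal's SD/mean
ratio is bounded by 1, and an SD that large signals right skew anyway). By
default this puts both volumes and the NIHSS on lognormal marginals and
disease duration (5.3 ± 3.1 days) on a truncated normal. Because monotone
margin transforms attenuate Pearson correlations, the latent correlations
are adjusted by numerically inverting the induced-correlation map
(Gauss-Hermite quadrature), so the *configured* product-moment correlations
are what the samples actually carry: ALPS-hemorrhage −0.426, ALPS-edema
−0.592, ALPS-contralateral 0.5, and NIHSS associations (−0.30 with ALPS,
0.55/0.50 with the volumes) chosen as clinically plausible values that keep
the joint matrix positive definite.

The relative edema ratio is **computed** from the simulated volumes, never
drawn, preserving its definitional identity. Its association with ALPS is
still a calibration target (−0.489): with both volumes lognormal the ratio
is lognormal too, and the latent hemorrhage-edema correlation that produces
the target ALPS-ratio correlation has a closed form; the default generator
solves it (landing near 0.80 on the product-moment scale, itself a
plausible hemorrhage-edema coupling).

The 90-day outcome is Bernoulli with
$\mathrm{logit}\,P(\mathrm{mRS} \le 2) = \beta_0 + \beta_1 \cdot
\mathrm{ALPS}$, where $\beta_1 = \ln(1.686)/0.1$ encodes the published
odds ratio per 0.1 index increase and $\beta_0$ is calibrated by root
finding so the marginal favorable fraction is 39/55 = 0.709, integrating
the logistic response over the ALPS marginal actually used (ipsilateral for
supratentorial cases, the two-side average for subtentorial ones). Whether
age or NIHSS entered the real outcome mechanism is not knowable from
summary statistics; their coefficients are exposed (`beta_age`,
`beta_nihss`) and default to zero. mRS grades within the favorable (0-2)
and poor (3-6) bands are uniform — the band, not the grade, is what the
analyses use.

Not emulated: longitudinal trajectories, missing data, site effects, and
any marginal shape information beyond mean ± SD (the true volume
distributions may be heavier- or lighter-tailed than lognormal).

## Statistical battery

* Two-sample comparisons default to the pooled Student's t and accept
  either raw vectors or `summary_group(n, mean, sd)` objects; both routes
  share one set of moment formulas, so summaries computed from raw data
  give bit-identical results. Welch's form is a flag.
* Correlations: Pearson r with the exact t transform; Spearman applies the
  same machinery to mid-ranks.
* 2x2 tables: uncorrected chi-square, Yates, and the exact hypergeometric
  test are all available; `"auto"` uses the exact test when any expected
  cell is below 5. Which variant produced any particular published p-value
  is usually unrecoverable, so none is asserted as canonical.
* Normality: the Kolmogorov-Smirnov distance against a normal with
  estimated parameters, with a seeded Monte-Carlo null (the classical KS
  null is anticonservative once parameters are estimated). The null table
  is cached per sample size, and the seed is recorded in the result.
* Logistic regression: maximum likelihood via IRLS, Wald intervals, and
  per-unit odds-ratio rescaling $\mathrm{OR}_s = \exp(s\beta)$ — the
  "per 0.1 increase" convention, identical to rescaling the predictor.
  Complete separation is detected (effect of one predictor SD exceeding 30
  logits, or exploding standard errors) and reported as an error naming
  the predictor; no penalized fallback is fitted.
* Covariate screening keeps candidates with univariate p < 0.1 plus a
  configurable always-include list (age, sex, baseline NIHSS by default),
  the conventional model-building rule for such studies.
* Two-sided tests throughout, alpha 0.05, no multiplicity correction.

## Problem sizes and numerical tolerances

The test suite exercises: exact noiseless round trips (tensor components
recovered to < 1e-10 mm^2/s; pipeline ALPS equal to the analytic index to
< 1e-6); 2% Rician noise at 20 seeds (ALPS within 0.05 of truth); 10,000
two-sample simulations at group sizes 46/97 for type-I calibration; 200
simulated cohorts of 55 patients for odds-ratio recovery; and cohorts of
5,000 per group for marginal/correlation recovery (means within 3 standard
errors, correlations within 0.03). These sizes keep the default suite
around half a minute while leaving Monte-Carlo margins comfortably inside
the asserted bands.

## Known limitations

The phantom's piecewise-constant geometry makes ROI extraction easier than
on real color-FA images, where placement is the dominant source of
operator variance. The log-linear estimator is biased at low SNR (the
Rician floor); the consistency test pins the bias below 2% at 1% noise,
but clinical SNR can be worse near hemorrhage. The cohort simulator
reproduces first and second moments and a single outcome mechanism — it
cannot validate distributional claims beyond those, and at n = 55 the
per-0.1 odds ratio is recovered with the upward small-sample bias typical
of maximum likelihood (median within 15% of the configured value).
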