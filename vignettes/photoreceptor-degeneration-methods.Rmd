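---
title: "Quantifying photoreceptor degeneration in ABCA4 retinopathy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying photoreceptor degeneration in ABCA4 retinopathy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ezprog)
```

## The problem

ABCA4-associated (Stargardt) retinopathy destroys photoreceptors
centrifugally. On en face OCT maps the lesion is visible as an area where
the ellipsoid zone (EZ) — equivalently, the photoreceptor outer segments
(OS) — is absent, but degeneration is not confined to that area: the
outer nuclear layer (ONL), inner segments (IS) and OS are thinned for
several degrees beyond the lesion boundary, while the retinal pigment
epithelium (RPE) shows a junctional thickening rim. `ezprog` implements a
pipeline that quantifies both the lesion itself and this junctional
degeneration, and links lesion chronology to the ABCA4 genotype:

1. **EZ-loss quantification** from OS thickness maps, by map thresholding
   and by the manual-grading Riemann-sum procedure;
2. **normative z-score standardization** and **contour-band features** at
   fixed distances from the lesion boundary, plus ETDRS subfield means;
3. **progression statistics**: Box-Cox profiling, square-root-area mixed
   models, per-band deficit and thinning-rate models;
4. an **additive allele-severity model** of the age of criterion EZ-loss,
   with patient-wise leave-one-out cross-validation.

Because no patient-level imaging data are distributed, the package ships
a synthetic-data generator whose defaults emulate the study design the
methods were developed for; every stage is tested against it.

## The synthetic-data generator

`sim_config()` fixes the study conditions:

* **Grid**: 37 B-scans x 512 A-scans over 30 x 15 degrees, B-scan spacing
  120 um, schematic-eye scaling 0.289 mm/degree.
* **Visit schedule**: a first visit per patient, a 6-month retest, then
  annual visits (5 by default) — the prospective natural-history design.
* **Lesion**: a fovea-centred disc whose radius grows linearly at
  `growth_rate / sqrt(pi)` mm/y past the eye's onset age `t0`, so
  sqrt(area) grows at `growth_rate` (log-normal across eyes, arithmetic
  mean 0.09 mm/y). OS thickness is exactly 0 inside the lesion. The age
  of criterion EZ-loss (sqrt area = 2.5 mm, i.e. 6.25 mm^2) is then
  exactly `t0 + 2.5 / growth_rate`. An eccentricity switch renders
  elliptical lesions for robustness tests; real lesions are irregular,
  but a convex lesion exercises every downstream operator.
* **Genotype**: each patient draws two variants from a pool; onset age is
  additive, `t0 = s(v1) + s(v2) + b_patient + e_eye` with Gaussian
  patient and eye shifts. The pool's null-class (6.88 y) and
  p.Gly1961Glu (34.63 y) severities are published values; the other pool
  entries are synthetic, chosen to span the plausible range so that
  pooling, shared alleles and cross-validation eligibility are exercised.
* **Junctional degeneration**: outside the lesion, at boundary distance
  `d` degrees, lamina `l` is perturbed by `A_l * exp(-d / tau_l)`
  normative SDs. The paper-facing summaries only pin down two points of
  each profile — the deficit at the first contour line (0.43 degrees) and
  the distance at which the mean returns within +/-2 z — and a
  two-parameter exponential reproduces both. Defaults are back-computed
  from those pairs: for the ONL, a first-contour deficit of -3.60 z and a
  crossing at 3.2 degrees give `A = -3.94`, `tau = 4.71`; the IS and OS
  use `tau = 1.50` and `0.90` (the decay scales keep the ONL > IS > OS
  ordering of spatial extent), the inner retina `tau = 1`, and the RPE a
  positive rim of +0.61 z at the first contour. For the inner retina the
  two published endpoints (deficit -1.54 z at 0.43 degrees, normalization
  at 1.07 degrees) cannot both hold under any monotone decay — a deficit
  already within +/-2 z normalizes at the first band — so the generator
  keeps the deficit and accepts first-band normalization; heterogeneity
  across real eyes, which the pooled per-eye average reflects, is not
  part of the generator's mean model.
* **Noise**: per-lamina Gaussian pixel noise, by default equal to the
  normative SD, so a healthy simulated eye scores z ~ N(0, 1); thickness
  is floored at 0. OS absence inside the lesion is exact (the
  segmentation produces hard zeros; sub-micron export noise can be
  accommodated with the `tol` argument of `ez_mask_from_os()`).
* **Flecks**: `insert_flecks()` plants zero-OS runs shorter than 250 um
  outside the lesion with at least 200 um of intact run on the fovea
  side — exactly the disruptions the B-scan grading rules are designed to
  forgive. Flecks are never inserted by `render_visit()` itself, because
  on the en face map a fleck is indistinguishable from lesion by the
  zero-thickness definition; they exist to exercise the B-scan rules.

What the generator does **not** emulate: irregular and multifocal lesion
shapes (the distance transform handles multifocality, but the generator
only produces discs/ellipses), anisotropic lesion growth, foveal sparing,
vignetting artifacts (the validity-mask path is exercised with synthetic
masks in tests), speckle, or segmentation error of the upstream neural
network. Passing tests therefore demonstrate correctness of the
quantification and inference machinery under the assumed data-generating
model, not segmentation robustness on real scans.

## Lesion quantification

A pixel is EZ-loss iff its OS thickness is `<= tol` (default exactly 0)
and valid. Pixels within 5 degrees of the optic disc and invalid pixels
are *missing*, never lesion or intact. The map-based area is pixel count
x pixel area; the B-scan route measures per-scan central discontinuity
lengths `X_k` and sums `X_k * DeltaX` (Riemann sum).

The discontinuity scan starts at each peripheral edge and moves toward
the fovea; the discontinuity starts at the first EZ-absent pixel, except
that an absent run strictly shorter than 250 um is forgiven when a
contiguous intact run of at least 200 um lies fovea-side of it (the
bounds follow the grading protocol's wording: "< 250 um" is strict, "at
least 200 um" is inclusive). `X_k` spans the two per-side starts; for a
gap confined to one side of the fovea it spans from the start to the
fovea-most absent pixel of that side — the protocol measures a single
central discontinuity and does not specify this case.

## Contour features

Thickness maps are standardized pointwise against a normative model
(`z = (t - mu(x, y, age)) / sigma(x, y)`; the model here is parametric,
with a linear age effect centred at 40 years and an ONL foveal peak).
Boundary distances are computed with an exact Euclidean distance
transform that honours the grid's strong anisotropy (B-scan spacing
~0.41 degrees vs A-scan pitch ~0.06 degrees); the separable
parabolic-envelope algorithm is implemented in the package because no
installed R routine offers anisotropic pitches, and it is property-tested
against a brute-force oracle.

Band `k` collects pixels at distances `((k - 0.5) * 0.43, (k + 0.5) *
0.43]` degrees — half-open annuli centred on multiples of a Goldmann III
stimulus diameter. Averaging over bands rather than along one-pixel
contour polylines uses every exterior pixel exactly once and is far more
stable on a 37-row grid. Pixels closer than 0.215 degrees to the boundary
belong to no band: they are closer than half a band width to the lesion
itself. Bands with fewer than `min_pixels = 10` analyzable pixels are
missing rather than noisy. The distance to normalization is the first
band whose mean |z| is at or below 2; eyes that never normalize within
the measured bands are censored, excluded from the normalization-distance
model and counted — one-sided inclusion would bias the average downward.

For rate-of-change models the bands are anchored to each eye's
*first-visit* boundary, so the same retinal locus is followed over time;
cross-sectional models use each visit's own boundary.

## Progression statistics

Box-Cox profiling transforms the area with `(area^lambda - 1) / lambda`
(log at 0), fits the random-intercept-and-slope model `y ~ time` with eye
nested in patient by ML for each lambda on a 0-1 grid (step 0.05), and
adds the Jacobian term `(lambda - 1) * sum(log(area))` so log-likelihoods
are comparable. Zero-area visits are excluded from profiling (the
transform is undefined) but included as 0 in sqrt-scale fits. Downstream
analyses always use the square-root transform regardless of the argmax,
mirroring the source analysis (whose optimum, lambda = 0.4, approximates
the square root); on generator output the argmax lands at 0.40-0.45.

All longitudinal models are `lme4` fits with random intercepts and slopes
for patient and for eye nested in patient; intercept-only summaries use a
patient random intercept with eyes as residuals (one value per eye makes
an eye-level intercept unidentifiable). Inference uses Satterthwaite
degrees of freedom via `lmerTest`. Degenerate inputs — noise-free
simulations, constant responses — can make the mixed fit impossible
(zero residual variance); the fitter then falls back to OLS with
normal-approximation inference and flags the result (`method = "ols"`).
ML is used for lambda profiling and model comparison, REML for reported
variance components. All fits are deterministic given the data.

## The allele-severity model

The age of criterion EZ-loss is imputed per eye by OLS of sqrt(area) on
age, solving for the criterion (2.5 mm); at least two visits with
measurable (positive) area are required, extrapolation is allowed in both
directions, and a non-positive slope yields a missing value with a reason
code. When any visit exceeds 16 mm^2 — lesions reaching the frame limits,
where the measured area saturates — the slope is taken from the first two
visits only and flagged. Imputation precision depends on how far the
criterion lies from the observed visits: when visits bracket the
criterion (as in the source cohort, whose average baseline sqrt-area of
3.3 mm already exceeds 2.5 mm) the per-eye error is a fraction of a year
and left/right eyes agree with R^2 > 0.9; for slow progressors far from
criterion the extrapolation error grows without bound, which is why
censoring-style reason codes are carried through.

The additive model regresses eye-level ages on allele counts — one column
per distinct variant, all protein-truncating/null variants pooled into a
single column, no intercept, a patient random intercept, eyes as
residuals — so a genotype prediction is the plain sum of its two allele
severities. Variants whose carriers all lack imputable ages are dropped
and reported, never silently imputed. The marginal R^2 is
`Var(fixed) / (Var(fixed) + Var(patient) + Var(residual))`.
Cross-validation is patient-wise: only patients whose both variants occur
in at least one other patient are eligible; the model is refit without
each patient and the held-out eyes predicted; `cv R^2 = 1 - SSE /
SST` with SST about the full eligible-sample mean. Comparisons with
external severity scales are made on the delay-of-disease-initiation
scale (severity minus the null severity), which is invariant to constant
shifts of either scale; ordinal external scales get per-category medians.

## Problem sizes and numerical choices

The test suite uses the full 37 x 512 grid wherever maps are rendered,
with 60-patient cohorts for parameter-recovery checks (progression rate,
contour deficit, normalization distance), 10 seeded replicates for the
Box-Cox optimum, 100 replicates for progression-rate recovery, and 200
replicates for allele-CI coverage at the study's 43-patient scale (CI
coverage near 95% cannot be distinguished from a 90% floor with fewer
replicates). Unit tests run on reduced grids (12 x 64) where the check is
structural rather than quantitative. Optimizer settings are `lme4`
defaults; singular fits are tolerated (variance components at boundary
are expected in small or noise-free simulations). Ties in the ETDRS
quadrant assignment (|x| = |y|) go to the horizontal quadrants; the nasal
direction is taken toward the optic disc.

## Known limitations

* The generator's circular, isotropically growing lesion understates the
  geometric variability of real disease; quantification on irregular
  lesions is exercised only through random-mask property tests.
* The published severity table is reproduced only for the two variants
  whose values appear as worked examples (null 6.88 y, p.Gly1961Glu
  34.63 y); other pool severities are synthetic.
* The Box-Cox profile uses a parametric Gaussian mixed model; the
  nonparametric-random-effect variant of the original analysis is out of
  scope, though the selection criterion (argmax log-likelihood) is the
  same.
* Distance-to-normalization is quantized to the 0.43-degree band grid, so
  recovered crossings are accurate to about one band width.

## A short worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_patients = 4, n_visits = 3, seed = 7)
nm  <- make_normative_model(cfg)
truth <- simulate_patient_cohort(cfg)
visit <- render_visit(truth[1, ], truth$t0[1] + 6, nm, cfg, seed = 11)
rec <- quantify_lesion(visit)
c(map = rec$area_mm2, riemann = rec$riemann_area_mm2)

d <- boundary_distance_map(rec$mask, visit$geometry)
z <- zscore_map(visit, nm)
head(contour_band_means(z, visit$thickness, d, rec$analyzable))
```
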