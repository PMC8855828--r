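# ezprog

Quantifying ellipsoid-zone (EZ) loss and photoreceptor degeneration in
ABCA4-associated (Stargardt) retinopathy from en face OCT layer
thickness maps.

## What it does

In ABCA4 retinopathy, photoreceptor loss shows up on en face OCT as an
area where the outer segments (OS) are completely absent — the EZ-loss
lesion — surrounded by a junctional zone in which the outer nuclear
layer (ONL), inner segments (IS) and OS are thinned for several degrees
beyond the boundary. `ezprog` implements, as a tested R package plus an
`analysis/` workflow, the full quantitative pipeline for this disease
picture:

- **EZ-loss quantification** — lesion masks from OS maps (absence =
  zero thickness), peri-papillary (5°) and validity exclusions, areas by
  pixel counting and by the B-scan-wise Riemann sum
  `Area = Σ_k X_k · ΔX` with the manual-grading break-forgiveness rules
  (absent runs < 250 µm are forgiven given ≥ 200 µm of intact EZ band
  fovea-side).
- **Normative z-scores and contour bands** — pointwise standardization
  `z = (t − μ(x, y, age)) / σ(x, y)`, an exact anisotropic Euclidean
  distance transform to the lesion boundary, layer means along contour
  bands spaced 0.43° (a Goldmann III stimulus diameter), distance to
  normalization (|z| ≤ 2), and ETDRS-grid subfield means.
- **Progression statistics** — Box-Cox profile likelihood over λ with
  the Jacobian correction, the square-root-area mixed model
  `√area ~ 1 + time` with random intercepts and slopes for patient and
  eye-in-patient (Satterthwaite inference via `lmerTest`), per-band
  deficit and thinning-rate models anchored to the first-visit boundary.
- **Genotype model** — per-eye imputation of the age of criterion
  EZ-loss (√area = 2.5 mm, i.e. 6.25 mm²; > 16 mm² triggers the
  first-two-visits rule), an additive allele-severity model
  `age = Σ allele severities + patient intercept + eye residual` with
  null-variant pooling, marginal R², patient-wise leave-one-out
  cross-validation, and comparison against external severity scales on
  the delay-of-disease-initiation scale.
- **Synthetic cohorts** — a generator emulating the study design
  (37 B-scans over 30° × 15°, 120 µm spacing, annual visits plus a
  6-month retest, √-linear lesion growth at 0.09 mm/y on average,
  genotype-additive onset ages, exponential junctional deficits), so
  every stage is testable end to end without patient data.

The methods vignette
(`vignettes/photoreceptor-degeneration-methods.Rmd`) documents the
models, parameter defaults and design choices in detail.

## Worked example

```r
library(ezprog)

cfg <- sim_config(n_patients = 4, n_visits = 3, seed = 7)
nm  <- make_normative_model(cfg)
truth <- simulate_patient_cohort(cfg)

# render one eye six years after onset and quantify its lesion
visit <- render_visit(truth[1, ], truth$t0[1] + 6, nm, cfg, seed = 11)
rec <- quantify_lesion(visit)
round(c(map = rec$area_mm2, riemann = rec$riemann_area_mm2), 4)
#>     map riemann
#>  0.2804  0.2804

# layer z-scores along contour bands outside the lesion
d <- boundary_distance_map(rec$mask, visit$geometry)
z <- zscore_map(visit, nm)
bm <- contour_band_means(z, visit$thickness, d, rec$analyzable)
head(bm[bm$lamina == "onl", ], 4)
#>    band distance_deg lamina mean_z mean_um n_pixels
#> 19    1         0.43    onl  -3.65    53.6      164
#> 20    2         0.86    onl  -3.34    52.5      202
#> 21    3         1.29    onl  -3.09    51.0      246
#> 22    4         1.72    onl  -2.87    49.2      304
```

Both area routes agree exactly on this convex lesion (0.28 mm²), and the
ONL is ~3.7 normative SDs thinner than normal directly outside the
boundary, recovering toward the normative band with distance.

Genotype predictions are plain sums of the published per-allele
contributions to the age of criterion EZ-loss:

```r
pub <- published_severities()
predict_age(c("null", "null"), pub)          # 13.76 years
predict_age(c("p.Gly1961Glu", "null"), pub)  # 41.51 years
```

## The analysis workflow

The `analysis/` scripts run the pipeline end to end on a synthetic
cohort, writing tables and figures under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R    # render + write the cohort tree
Rscript analysis/02_quantify_lesions.R   # lesion areas, both routes
Rscript analysis/03_contour_features.R   # z-scores, contour bands, ETDRS
Rscript analysis/04_progression_models.R # Box-Cox, √-area + band models
Rscript analysis/05_allele_model.R       # imputation + additive model
```

`run_pipeline(pipeline_config(...), out_dir)` performs the same stages
in one call.

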