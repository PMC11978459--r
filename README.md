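# surfmorph

Landmark-free statistical shape analysis of skeletal-muscle surface meshes.

Muscle shape — how wide, thick, twisted or elongated a muscle belly is —
varies between people and with ageing, and carries functional information
that volume alone misses. Smooth muscle surfaces offer almost no reliable
anatomical landmarks, so surfmorph implements the landmark-free route for
researchers working with MRI-derived surface segmentations:

* **Generalized Procrustes surface analysis (GPSA)** — a prototype surface is
  chosen, every specimen is superimposed onto it by iterative closest point
  (ICP) registration, correspondence is *constructed* by matching each
  prototype vertex to its nearest specimen point ("homologization"), and the
  prototype is iteratively reformed into the sample's average surface.
* **Symmetric Procrustes surface metric** — interspecimen dissimilarity

  d(A,B) = sqrt( ½ [ (1/|A|) Σₐ min_b ‖a−b‖² + (1/|B|) Σ_b min_a ‖b−a‖² ] )

  in which each surface carries equal total weight, so surfaces with
  different vertex counts compare fairly.
* **Principal coordinates ordination** (Gower double centering) of the
  distance matrix, with theoretical extreme-shape reconstruction along any
  axis and per-vertex variation heat maps exportable as mesh scalar fields.
* **Covariate models** — each ordination axis regressed on log(mass), age
  group, sex, muscle volume, physical activity (MET·min/week), height and the
  age×sex interaction, with marginality-respecting backward stepwise
  reduction (AIC or significance criterion), per-term partial r² =
  t²/(t²+df), automatic t-test / Mann–Whitney group comparisons, and
  residual-effect-plot data export.
* **A synthetic muscle-population generator** with known latent shape factors
  (girth, axial torsion, elongation), cohort-style group structure and
  correlated covariates, so every stage is validated against ground truth.
* Mesh I/O for PLY (ascii + binary little-endian), STL, OBJ and legacy VTK,
  and an end-to-end, seed-reproducible pipeline (`run_pipeline()`, plus a CLI
  at `inst/cli/surfmorph.R`).

## Worked example

Simulate a cohort-style population (21 young, 15 older; the older group
shifted toward less proximal torsion), run the full analysis, and relate the
shape axes to the participants:

```r
library(surfmorph)

cfg <- population_config(
  n_young = 21, n_older = 15,
  factor_sds = c(girth = 1, torsion = 1, elongation = 0),
  effects = list(age_group = list(older = c(torsion = -2))),
  vertex_count_range = c(800, 1600),
  seed = 5
)
pop    <- generate_population(cfg)
gpsa   <- generalized_align(population_meshes(pop))   # prototype auto-selected
ord    <- pcoa(gpsa$distances)
tidy(ord)[1:3, ]
#> # A tibble: 3 × 4
#>   axis  eigenvalue pct_variance cum_pct_variance
#>   <chr>      <dbl>        <dbl>            <dbl>
#> 1 PC1      0.00906        35.1              35.1
#> 2 PC2      0.00358        13.9              48.9
#> 3 PC3      0.00132         5.10             54.0

fit <- backward_stepwise(fit_shape_glm(ord_scores(ord), pop$covariates, axis = "PC2"))
tidy(fit)
#> # A tibble: 2 × 6
#>   term           estimate std.error statistic    p.value partial.r2
#>   <chr>             <dbl>     <dbl>     <dbl>      <dbl>      <dbl>
#> 1 (Intercept)    -0.00580   0.00162     -3.57 0.00108         0.273
#> 2 age_groupolder  0.0139    0.00252      5.54 0.00000346      0.474
```

PC1 captures girth (its scores correlate with the generator's true girth
factor at |r| = 0.999 in this run) and explains 35.1% of shape variance; PC2
is the torsion axis (|r| = 0.965 with the true torsion factor): stepwise
reduction keeps only the age-group term, whose positive coefficient recovers
the injected older-group shift with a partial r² of 0.47 at p = 3.5 × 10⁻⁶.
Scores are in unit-RMS-radius shape units (size is normalized away), hence
the small absolute magnitudes. `reconstruct_shape_at_score()`
and `variation_heatmap()` turn any axis into min/max extreme surfaces with a
per-vertex displacement field, written as VTK scalars by `run_pipeline()` for
blue-to-red heat-map rendering.

(Output printed by this code under the shown seed; small numeric differences
across BLAS builds are possible.)

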