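---
title: "Landmark-free statistical shape analysis of muscle surfaces: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark-free statistical shape analysis of muscle surfaces: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfmorph)
```

## The problem

Skeletal muscles differ between people in ways that a single volume or length
number cannot express: one person's medial gastrocnemius is wider and thicker,
another's is twisted about its long axis near the knee, a third's is long and
slender. Classical geometric morphometrics quantifies such differences from
homologous landmarks, but a smooth muscle belly offers almost no reliable
landmarks. surfmorph implements the landmark-free alternative: whole triangulated
surfaces are compared directly, correspondence is *constructed* by the analysis
rather than assumed, and the resulting interspecimen distances are ordinated
and regressed on participant covariates.

The pipeline has four stages:

1. **Conditioning** (`read_mesh()`, `smooth_mesh()`, `reflect_sagittal()`):
   surfaces are cleaned, optionally smoothed, and left-side specimens are
   mirrored so all muscles share one anatomical frame.
2. **Generalized Procrustes surface analysis** (`generalized_align()`): a
   prototype surface is chosen, every specimen is rigidly superimposed onto it
   by iterative closest point (ICP), each specimen is *homologized* — for every
   prototype vertex, the nearest specimen point is recorded — and the prototype
   is reformed as the average of the homologized points. The loop repeats until
   the average surface stops changing. Interspecimen dissimilarity is the
   symmetric Procrustes surface metric
   $$ d(A,B) \;=\; \sqrt{\tfrac12\Big[\tfrac1{|A|}\sum_{a\in A}\min_{b\in B}\lVert a-b\rVert^2
      \;+\; \tfrac1{|B|}\sum_{b\in B}\min_{a\in A}\lVert b-a\rVert^2\Big]}, $$
   in which each surface carries equal total weight, so surfaces with different
   vertex counts are compared fairly.
3. **Ordination** (`pcoa()`): Gower's principal coordinates analysis of the
   distance matrix — double-center the squared distances,
   $B=-\tfrac12 J (D\circ D) J$, and eigendecompose. When the distances are
   Euclidean this is exactly PCA of the underlying configuration, which is the
   main correctness oracle in the test suite.
4. **Covariate models** (`fit_shape_glm()`, `backward_stepwise()`): each
   retained axis is regressed on log mass, age group, sex, muscle volume,
   physical activity (MET·min/week), height and the age-by-sex interaction,
   followed by backward stepwise reduction; per-term partial $r^2$ is
   $t^2/(t^2+\mathrm{df})$.

## Choices the method forces, and how they were made

**Metric weighting.** "Symmetric" weighting is implemented as uniform
$1/|A|$, $1/|B|$ weights per surface with the $\tfrac12$ symmetrization above:
the simplest scheme that makes the metric independent of which surface is
denser. Per-vertex area weighting was considered and is deliberately *not* the
default: the metric's vertex-set semantics keep it exactly checkable against a
brute-force double loop.

**Size.** Muscle size is removed once, up front, by scaling every pose-normalized
specimen to unit root-mean-square vertex radius (`normalize_pose(unit_scale = TRUE)`).
The classical centroid size — the square root of *summed* squared distances to the
centroid, `centroid_size()` — grows with the number of vertices, so scaling to unit
centroid size would make densely sampled specimens systematically smaller than
sparsely sampled ones and manufacture a spurious "sampling density" ordination
axis. The RMS radius (centroid size divided by $\sqrt{n}$) is the
sampling-invariant analogue and is what the pipeline uses; this was confirmed
empirically during development, where unit-centroid-size scaling produced a
dominant artefactual axis correlated at $r \approx 0.96$ with $1/\sqrt{n}$.
Scaling can be disabled (`scale_normalize = FALSE`) for allometric questions.

**Initial pose.** ICP only converges locally, so specimens are first centered
and rotated so their principal axes meet the coordinate axes, longest axis to
z (`normalize_pose()`). Axis *signs* are fixed by the sign of the third central
moment computed with surface-area vertex weights. Area weighting matters:
meshes whose rings of vertices are evenly spaced along the length have a
symmetric *vertex* distribution even when the surface tapers asymmetrically,
and raw vertex moments then flip the long-axis sign unpredictably between
samplings of the same shape.

**Convergence.** ICP stops when the symmetric metric improves by less than
`tol = 1e-6` (relative) or after `max_iter = 100`; the best transform seen is
kept, so the reported metric sequence is non-increasing by construction. The
GPSA outer loop stops when the reference surface moves less than `tol = 1e-3`
RMS in working-frame units (0.1% of the surface RMS radius — about 0.08 mm at
muscle scale, well below segmentation accuracy) or when the improvement per
iteration falls under 10%: nearest-neighbour correspondences flip
discretely between iterations, which leaves the reference jittering at a small
floor that a fixed absolute tolerance alone would never cross.

**Ties and signs.** Homologization breaks nearest-neighbour ties by the lowest
vertex index. Each ordination axis is oriented so the specimen with the largest
absolute score is positive; score signs are therefore deterministic and plots
reproduce in the same orientation. Negative PCoA eigenvalues (the surface
metric need not be Euclidean) are dropped and their total magnitude is recorded
in `negative_mass`; percent variance is taken over the positive eigenvalues,
the standard Gower convention.

**Prototype.** The prototype should be the most "average" specimen:
`select_prototype()` superimposes every ordered pair once (no prototype
averaging), symmetrizes, and picks the specimen with the smallest mean
distance to all others; `rank = 2` supports falling back to the runner-up when
the first choice is visually anomalous. A full GPSA per candidate is available
(`method = "full"`) and is what `prototype_sensitivity()` uses to tabulate how
the percent variance of the leading axes depends on the prototype choice.
Screening a candidate prototype for anomalies remains a visual check on the
exported heat maps; it is not automated.

**Smoothing.** The σ (mm) of Gaussian-style smoothing is mapped to an
iteration count $n=\mathrm{round}\big((\sigma/\bar e)^2\big)$ of
Taubin smoothing ($\lambda = 0.5$, $\mu = -0.53$), where $\bar e$ is the mean
edge length — the diffusion length of iterated neighbourhood averaging grows
with $\sqrt{n}\,\bar e$. Taubin's sign-alternating steps keep the enclosed
volume of a closed surface within about 2% at σ = 2 mm (a tested property);
plain Laplacian smoothing is available and shrinks surfaces monotonically.
A separate GUI-style "surface smoothing factor" is a rendering option, not a
second physical parameter, and is folded into the single σ.

**Models.** Age enters as the binary young/older cohort indicator (reference
`young`; `female` is the sex reference), matching a two-cohort design;
continuous age would be a one-line change in the covariate table. Stepwise
reduction defaults to AIC (the behaviour of the standard `step()`), with an
`alpha` mode that drops the largest-p term until all remaining terms are
significant; both respect marginality (an interaction goes before its main
effects, main effects stay while their interaction remains). No
multiple-testing correction is applied across axes or muscles, and the fitted
object records that.

## What the synthetic generator emulates — and what it does not

`generate_population()` produces fusiform, closed, muscle-like surfaces with
three latent shape factors and cohort-style covariates:

* **girth** scales the cross-section (width and thickness together);
* **torsion** twists the cross-sections about the long axis, confined to the
  proximal 40% of the muscle with a linear ramp;
* **elongation** stretches the centerline.

Cross-sections are ellipses (55 × 35 mm at the belly of a 250 mm muscle,
medial-gastrocnemius-like proportions) modulated by a fixed 25% third-harmonic
radial asymmetry. The asymmetry is essential, not cosmetic: a perfectly
elliptical section maps onto itself under small rotations, so axial twist
would displace the surface almost purely tangentially and be invisible to any
closest-point metric. Real muscle cross-sections are strongly non-elliptic.
The asymmetry is oriented (`sin 3φ`) so the torsion-free shape keeps its
sagittal mirror plane, which the reflection tests rely on. `torsion_max`
defaults to 0.6 rad (≈34°) at one latent SD — inside anatomically reported
axial-torsion ranges — calibrated so that one SD of torsion is a clear shape
mode of the same order as girth rather than sub-noise detail.

Covariates are linked to shape the way anthropometry is: height correlates
with realized muscle length at $r = 0.8$ within group by construction; body
mass is lognormal around a height-linked mean; MET·min/week is group-dependent
(young more active); muscle volume is *measured* from each generated mesh by
the divergence theorem, so the volume–girth correlation is an emergent,
testable property. Group sizes default to 21 young and 15 older, 60% male.
Each specimen gets an independent vertex count (default 300–600; the
validation studies below use 800–1600) on a staggered ring grid, so no two
specimens share point correspondence — the property that makes the analysis
landmark-free in the first place. A nuisance rigid pose (uniform random
rotation, ±50 mm translation) is applied last, and every draw derives from the
config seed, so populations are bit-reproducible.

What the generator does **not** emulate: segmentation artefacts and topological
noise, regional (non-affine) hypertrophy, curved centerlines, aponeurosis
imprints, intramuscular fat, or marching-cubes-style irregular triangulations.
Passing the synthetic recovery tests therefore demonstrates that the
*statistical machinery* is sound — exact metric and ordination algebra, pose
recovery, factor recovery, calibrated error rates — not that any particular
anatomical claim about real muscles transfers.

## Problem sizes and tolerances used in validation

The test-suite studies run at sizes chosen to make their claims sharp while
keeping a full run comfortable on a laptop: metric-oracle checks on meshes of
≤ 30 vertices (exact, 1e-12); registration recovery over 100 seeded poses of a
500-vertex surface (rotation error < 1e-3 rad in ≥ 95); ordination oracles on
50 seeded Euclidean configurations (Procrustes residual < 1e-9); exact GPSA
recovery with 12 identically shaped specimens (pairwise distances < 1e-6);
factor recovery and group-effect power at n = 30 specimens of 800–1600
vertices (best |r| > 0.9; a 2 SD older-group torsion shift detected at
p < 0.01 in ≥ 90% of 20 replicates); type-I retention measured over 200
score-level null replicates (≤ 10% under the alpha criterion); and stepwise
agreement with exhaustive AIC enumeration over all marginality-respecting
submodels on 20 seeded problems. `scripts/acceptance.R` recomputes all of
these from scratch under a caller-supplied seed.

## Known limitations

* The vertex-to-vertex metric has a sampling-noise floor proportional to the
  local vertex spacing; at a few hundred vertices per specimen, shape modes
  displacing the surface by less than that spacing blur together. Denser
  sampling (or the point-to-triangle correspondence option, for ICP) mitigates
  this.
* GPSA results depend on the prototype; `prototype_sensitivity()` quantifies
  that dependence but cannot remove it.
* ICP with principal-axes initialization assumes clearly anisotropic shapes;
  near-spherical surfaces are flagged but their pose is genuinely ambiguous.
* The reconstruction of extreme shapes (`reconstruct_shape_at_score()`) is a
  per-vertex linear model in the score; strongly nonlinear modes (large
  rotations) are linearized.
* Models assume Gaussian errors and independence across specimens; no
  correction is applied across axes or muscles.
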