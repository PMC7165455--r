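---
title: "Mapping and comparing trabecular BV/TV distributions across the femoral head"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping and comparing trabecular BV/TV distributions across the femoral head}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(trabmap)
```

## The problem

Trabecular bone remodels under habitual load, so the *spatial
distribution* of bone volume fraction (BV/TV) across an epiphysis
records how a joint was loaded in life.  In the femoral head this
distinction is stark: habitual bipeds concentrate subchondral bone in a
single posterosuperior-medial region — one internal "pillar" — whereas
great apes that load the hip across a wide flexion range show two
concentrations, anterior and posterior on the superior surface, which
continue internally as two pillars.  Mean BV/TV over a single cube of
bone misses this completely; what separates the phenotypes is where the
bone is, not how much of it there is.

`trabmap` implements the whole chain needed to quantify that signal
from a segmented (binary) volume:

1. **Whole-head BV/TV field** — BV/TV is measured in overlapping
   spheres centred on a coarse background lattice and interpolated onto
   a fine element mesh filling the head, giving a BV/TV distribution
   map.
2. **Internal regions** — elements above a per-specimen quantile of the
   BV/TV values visualize where the highest bone volume sits; counting
   their connected components reads out the one-pillar/two-pillar
   dichotomy.
3. **Correspondence** — a template of 5 fixed landmarks, 28 boundary
   (curve) semilandmarks and 208 surface semilandmarks is projected on
   each specimen's subchondral surface, relaxed by thin-plate-spline
   (TPS) bending energy and slid to minimize Procrustes distance, so
   the same anatomical locations are compared across specimens.
4. **RBV/TV statistics** — BV/TV at each landmark is divided by the
   specimen's mean landmark BV/TV (RBV/TV, mean exactly 1 per
   specimen), the specimens-by-landmarks matrix is summarized by
   covariance PCA, and groups are compared by Bonferroni-corrected
   pairwise permutational MANOVA on the leading principal components.
5. **Fabric** — a mean-intercept-length (MIL) fabric tensor and degree
   of anisotropy DA = 1 − λ₃/λ₁ summarize strut alignment.

The anatomical frame is fixed throughout: +x medial, +y anterior, +z
superior; all lengths in millimetres.

## Reference parameters

| parameter | default | unit | why |
|---|---|---|---|
| sampling sphere diameter | 7.5 | mm | large enough to average several trabecular spacings, small enough to resolve the pillar scale |
| background grid spacing | 3.5 | mm | about half the sphere diameter: neighbouring spheres overlap, so the field is continuous |
| scalar mesh element size | 1.0 | mm | fine relative to the grid; the per-element value, not element shape, drives everything downstream |
| internal-region percentile | 80 (75/85 available) | — | per-specimen quantile: thresholds adapt to each individual's range and are robust to outliers |
| template counts | 5 + 4×7 + 208 (32 on dividers) | — | fixed corners at the head-neck boundary extrema, apex at the articular pole, quarters divided by meridians |
| permutations | 9999 | — | p floor ≈ 1e-4 with the add-one convention |
| PCs tested | 3 | — | default rule; a cumulative-variance (>50%) rule is available |

`pipeline_config()` collects these; every number above is overridable.

## The synthetic specimen generator

No scan data ship with the package; the generator produces femoral-head
stand-ins with *known* ground truth so that every downstream stage is
testable end to end.

A specimen is a hemispherical head (default radius 18 mm, superior
half-space) with a cylindrical neck stub (10 mm long, 9 mm radius)
extending inferiorly, voxelised at 0.3 mm.  The target BV/TV field is

```
field(x) = clip(base + Σ_k amp_k · exp(−d_k(x)² / (2 σ_k²)), 0.02, 0.95)
```

where `d_k` is the distance to blob centre *k*, optionally shrunk along
an elongation axis so the blob becomes a pillar.  Pattern defaults,
chosen once for clear phenotype recovery (the magnitudes of the real
concentrations are not published) and fully configurable:

* `human_one_pillar`: one blob in direction (+0.5, −0.5, +0.7)
  (posterosuperior-medial), depth 0.25 of the radius, amplitude 0.35
  over a base of 0.20, σ = 4.5 mm, elongated ×2.5 along the
  superoinferior axis.
* `ape_two_pillar`: the same blob at (0, +0.7, +0.7) and (0, −0.7,
  +0.7) — anterior and posterior superior, 90° apart.

σ = 4.5 mm keeps the two ape pillars separated at the 80th percentile
even under the cohort generator's inter-individual jitter (blob
directions rotated by N(0, 4°), amplitudes and widths scaled by
N(1, 5%)); with σ ≳ 5 mm the saddle between the pillars approaches the
threshold and the readout becomes fragile.

Trabecular texture is a thresholded Gaussian random field: bone at x iff
G(x) < Φ⁻¹(field(x)), with G a unit-variance field of correlation
length 0.3 mm.  Its expected local fill fraction equals the target
field *exactly*, which is all the BV/TV machinery can see; individual
struts are not modelled.  The correlation length is set at the strut
scale deliberately: each 7.5-mm sphere then averages on the order of a
hundred independent texture cells, giving per-node BV/TV estimator
noise of a few percent, comparable to counting statistics in real
scans.  A coarser texture (≳0.6 mm) leaves so few independent cells per
sphere that node estimates carry ~0.1 sd and speckle the percentile
regions.

What the generator does **not** emulate: a cortical shell, the fovea
capitis, growth-plate remnants, scanner noise, beam hardening, or
anisotropic strut architecture tied to the pillars.  Tests passing on
synthetic cohorts therefore validate the *pipeline's* correctness and
sensitivity, not the biological effect size in real scans.

## Numerical choices

* **Sphere counting rule** — a voxel belongs to a sampling sphere iff
  its centre is within the radius; the denominator is restricted to the
  outer mask so near-surface values are not diluted by air.  Matches a
  brute-force triple-loop count bitwise.
* **Node validity floor** — lattice nodes whose sphere covers less than
  25% of a full sphere's voxel count (slivers at the boundary) are
  sampled but excluded from interpolation: their estimator variance is
  several times the interior value and they otherwise imprint spurious
  high-BV/TV patches.
* **Grid anchoring** — the background lattice is anchored at the
  volume's first voxel centre (image-anchored), so node placement is
  invariant under translating the scan and a spacing larger than the
  mask extent correctly yields "no nodes".
* **Interpolation** — trilinear within complete grid cells; elsewhere
  inverse-distance weighting (power 2, 8 nearest valid nodes).  Both
  are convex combinations, so element values never overshoot the
  contributing nodes.  The scalar mesh uses cubic 1-mm elements; any
  mesh whose elements carry one BV/TV value each satisfies the same
  contract.
* **Mesh domain** — the scalar mesh covers the head proper (above the
  head-neck plane, z ≥ 0 by convention).  The neck stub exists to make
  the boundary geometry realistic, not to be analysed.
* **Quantile convention** — R's default linear-interpolation quantile
  (type 7); elements strictly above the threshold are flagged.  On a
  tie-free field of 10,000 values the 80th percentile flags exactly
  2,000.
* **Region counting** — components are 6-adjacent flagged elements;
  components smaller than 8 elements (8 mm³, far below the ~(4.5 mm)³
  blob scale) are reported in the size table but not counted as
  pillars.
* **Surface extraction** — marching tetrahedra (six tetrahedra per
  cell, consistent shared diagonal, watertight) followed by Taubin
  smoothing (λ = 0.5, μ = −0.53, 30 pass-pairs), which removes the
  voxel staircase while preserving enclosed volume to well under 5%.
  This replaces screened-Poisson-style reconstruction; the downstream
  contract — a smooth watertight subchondral surface — is the same.
* **TPS convention** — 3D kernel U(r) = −r, which is conditionally
  positive definite under the affine side conditions, so bending energy
  is non-negative and exactly zero for affine maps.
* **Sliding** — surface semilandmarks move in the tangent plane of
  their surface point, curve semilandmarks along the head-neck rim
  tangent, fixed landmarks never; every step re-projects to the
  surface and is accepted only if the objective decreased (step
  halving, 6 attempts).  Relaxation minimizes bending energy against
  the template; cohort sliding minimizes Procrustes distance to the GPA
  mean.  Tolerances: relative objective change < 1e-6 and 20 iterations
  at the operation level; the pipeline uses 1e-3 and 10 iterations —
  semilandmark positions stop moving at BV/TV-relevant scales long
  before the energy plateaus to machine precision.
* **GPA** — centre, optionally unit-scale, rotate (reflections
  forbidden) to the evolving mean until the mean moves < 1e-10.
* **PCA** — covariance (unscaled): all variables are RBV/TV on the same
  scale, and per-specimen standardization already happened.  Component
  signs follow a deterministic largest-loading-positive convention.
* **Permutational MANOVA** — Anderson's pseudo-F from the Euclidean
  distance matrix of the pair's PC scores, F = SS_between/(SS_within /
  (N−2)); p = (1 + #[F* ≥ F]) / (1 + n_perm) under label permutation,
  Bonferroni-multiplied by the number of pairs performed.  PC scores
  are computed once on the full sample, not per pair.  Permutations
  that reproduce the observed split tie with it, so the attainable
  minimum p sits just above 1/(n_perm + 1).  Groups with zero
  within-group scatter are reported as degenerate rather than p = 0.
  An exact-enumeration mode replaces sampling for small N.
* **MIL fabric** — 129 directions (subdivided octahedron, closed under
  the octahedral group), parallel test lines traced by stepping one
  voxel along the dominant axis; MIL(v) = in-region line length /
  phase changes; ellipsoid fitted by least squares to MIL⁻²;
  DA = 1 − λ₃/λ₁.  A fitted eigenvalue forced to ≤ 0 by an effectively
  unbounded MIL (e.g. uninterrupted struts) is clamped to a tiny
  positive curvature, giving DA → 1.

## Known limitations

* The published description of this landmark scheme counts 242 points
  while its components (5 + 28 + 208) sum to 241; the template is
  configuration-driven with those component defaults, and we do not
  invent a 242nd point.
* MIL line tracing rounds line samples to the nearest voxel, so DA is
  invariant under 90° volume rotations only to discretisation accuracy
  (measured ≈ 2×10⁻³ on thresholded random fields; the test bound is
  0.01), not to machine precision.
* Fixed-landmark detection assumes the head-neck boundary lies near a
  known plane (z = rim_z), which the synthetic generator guarantees;
  real scans must be reoriented to the anatomical convention first.
* The smallest attainable permutation p is bounded by n_perm and by
  tied splits; with 9999 permutations and 10+10 specimens this is far
  below 0.05 and irrelevant in practice.

## Problem sizes used by the test-suite

Module tests run on 9-mm heads at 0.45-mm voxels (≈43³ voxels,
seconds per specimen) with blob contrast raised to compensate for the
few independent texture cells per (smaller) sampling sphere.  The
recovery and statistics checks run the reference conditions — 10 + 10
specimens, 18-mm heads, 0.3-mm voxels, default generator parameters,
9999 permutations — as does `scripts/acceptance.R`.  The type-I-error
calibration uses 1,000 null data sets of 8 + 8 points with 199
permutations each.
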