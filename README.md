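# trabmap

Whole-epiphysis mapping and comparison of trabecular bone volume
fraction (BV/TV) distributions, for biological anthropologists and bone
biomechanists working from segmented micro-CT volumes.

Trabecular bone remodels under habitual load, so *where* bone is
concentrated inside a joint records how that joint was used.  In the
femoral head the signal is categorical: habitual bipeds concentrate
subchondral bone in one posterosuperior-medial region that continues
internally as a single pillar, while great apes that load the hip both
extended and deeply flexed show two concentrations — anterior and
posterior on the superior surface — continuing as two pillars.  trabmap
quantifies this from a binary volume and tests group differences:

1. **BV/TV distribution map** — BV/TV sampled in 7.5-mm spheres on a
   3.5-mm background grid, interpolated onto a 1-mm element mesh of the
   head interior.
2. **Internal regions** — per-specimen quantile threshold (default the
   80th percentile); connected components of the flagged elements count
   the pillars.
3. **Sliding semilandmarks** — a template of 5 fixed landmarks, 4
   boundary semicurves × 7 semilandmarks, and 208 surface semilandmarks
   (32 on the quarter-dividing meridians) is projected on the
   subchondral surface, relaxed by thin-plate-spline bending energy,
   and slid to minimize Procrustes distance across the cohort.
4. **RBV/TV statistics** — per-landmark BV/TV divided by the specimen
   mean (RBV/TV, row mean ≡ 1), covariance PCA, and Bonferroni-corrected
   one-way pairwise permutational MANOVA (Anderson's pseudo-F,
   F = (SS_B/(a−1))/(SS_W/(N−a)), p from label permutations with the
   add-one convention) on the first three PCs.
5. **Fabric anisotropy** — mean-intercept-length ellipsoid over 129
   quasi-uniform directions; DA = 1 − λ₃/λ₁.

A synthetic femoral-head generator (hemisphere + neck stub, baseline
BV/TV plus Gaussian concentration "pillars", thresholded Gaussian
random-field texture with analytically known fill fractions) provides
cohorts with ground truth, so the whole chain is testable without scan
data.  Anatomical frame everywhere: +x medial, +y anterior, +z superior.

## Worked example

Simulate three specimens of each phenotype at the reference geometry
(18-mm head radius, 0.3-mm voxels) and run the full pipeline:

```r
library(trabmap)
specs <- list(human = specimen_spec("human_one_pillar"),
              ape   = specimen_spec("ape_two_pillar"))
cohort <- make_cohort(3, specs, master_seed = 7)
res <- analyze_cohort(cohort, pipeline_config(n_perm = 999))
print(res)
```

```
<epiphysis_comparison> 6 specimens in 2 group(s)
  PC1-3 variance: 91.2% / 3.4% / 2.2%
  internal components (rows = group):

        1 2
  ape   0 3
  human 3 0
  pairwise permutational MANOVA:
  group_a group_b n_a n_b        F   p p_adjusted degenerate
1     ape   human   3   3 64.22187 0.1        0.1      FALSE
```

Every human-pattern specimen shows one internal high-BV/TV component at
the 80th percentile and every ape-pattern specimen two — the
one-pillar/two-pillar dichotomy.  PC1 of the RBV/TV matrix carries 91%
of the variance and separates the groups; the permutation p of 0.1 is
the floor attainable with three specimens per group (2 of the 20
distinct label splits tie with the observed one) — larger cohorts reach
conventional significance, as the acceptance run below shows.

For the file-based workflow (NIfTI/TIFF volumes + manifest CSV, cached
stages, Markdown report) see the numbered drivers under `analysis/`:
`01_simulate.R`, `02_pipeline.R`, `03_report.R`.

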