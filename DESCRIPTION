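Package: trabmap
Title: Whole-Epiphysis Trabecular Bone Mapping and Landmark-Based
    Comparison of BV/TV Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps the spatial distribution of trabecular bone volume
    fraction (BV/TV) across a whole epiphysis from binary micro-CT-like
    volumes, using sampling spheres on a regular background grid
    interpolated onto a fine element mesh.  Places a template of fixed
    landmarks and sliding semilandmarks on the subchondral surface,
    relaxes semilandmarks by thin-plate-spline bending energy and slides
    them to minimise Procrustes distance, extracts relative BV/TV
    (RBV/TV) at landmarks, and compares groups by principal component
    analysis and Bonferroni-corrected pairwise permutational MANOVA.
    Includes a synthetic femoral-head generator with known ground-truth
    BV/TV fields (one-pillar and two-pillar concentration phenotypes),
    percentile-based internal region extraction, and mean-intercept-length
    fabric anisotropy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    igraph,
    jsonlite,
    RNifti,
    tiff
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ggplot2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
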