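# shared fixtures, built once per test run (memoised in this environment)
.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# small synthetic head (radius 9 mm) keeps surface/landmark tests fast;
# blob geometry scaled to the head so the phenotypes stay recoverable
small_spec <- function(pattern = "human_one_pillar", seed = 1L) {
  blobs <- switch(pattern,
    uniform = list(),
    human_one_pillar = list(small_blob(c(0.5, -0.5, 0.7))),
    ape_two_pillar = list(small_blob(c(0, 0.7, 0.7)),
                          small_blob(c(0, -0.7, 0.7))))
  # contrast is boosted relative to the reference scale: a 9-mm head
  # holds far fewer independent texture cells per sampling sphere
  specimen_spec(pattern, head_radius_mm = 9, voxel_mm = 0.45,
                base_bvtv = 0.15, blobs = blobs, texture_corr_mm = 0.25,
                neck_length_mm = 5, neck_radius_mm = 4.5, seed = seed)
}

small_blob <- function(dir) {
  list(dir = dir / sqrt(sum(dir^2)), depth = 0.25, amplitude = 0.45,
       sigma_mm = 2.25, elong_axis = c(0, 0, 1), elong_factor = 2.5)
}

small_mask <- function() fixture("small_mask", function()
  make_head_mask(9, 5, 4.5, 0.45))

small_volume <- function(pattern = "human_one_pillar", seed = 1L) {
  key <- paste0("vol_", pattern, "_", seed)
  fixture(key, function() {
    mask <- small_mask()
    tr <- target_field(small_spec(pattern, seed), mask)
    synthesize_trabeculae(tr, mask, 0.25, seed = seed)
  })
}

small_config <- function(...) pipeline_config(
  grid_spacing_mm = 2.5, sphere_diameter_mm = 5, mesh_size_mm = 1,
  n_perm = 499, relax_iters = 5, slide_rounds = 1, ...)

small_surface <- function() fixture("small_surface", function()
  extract_subchondral_surface(small_mask(), smoothing_iters = 30))

# voxelised sphere mask of radius r (voxel size vox), centred on origin
sphere_mask <- function(r = 10, vox = 0.5) {
  half <- ceiling(r / vox) + 1L
  xs <- (-half:half) * vox
  d2 <- outer(outer(xs^2, xs^2, "+"), xs^2, "+")
  list(arr = array(as.integer(d2 <= r^2), rep(length(xs), 3)),
       vox = vox, origin = rep(xs[1], 3), r = r)
}

# deterministic random landmark configurations
rand_shape <- function(n = 20, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * 3), n, 3)
}

# brute-force triple-loop oracle for sphere-sampled BV/TV
bvtv_oracle <- function(vol, center, diameter_mm) {
  m <- if (!is.null(vol$outer_mask)) vol$outer_mask
       else array(TRUE, dim(vol$voxels))
  b <- vol$voxels > 0 & m
  n <- dim(b); r2 <- (diameter_mm / 2)^2
  nb <- nt <- 0L
  for (i in 1:n[1]) for (j in 1:n[2]) for (k in 1:n[3]) {
    pos <- vol$origin_mm + (c(i, j, k) - 1) * vol$voxel_mm
    if (sum((pos - center)^2) <= r2) {
      if (m[i, j, k]) {
        nt <- nt + 1L
        if (b[i, j, k]) nb <- nb + 1L
      }
    }
  }
  c(nb, nt)
}

# small regular scalar mesh with random values
toy_mesh <- function(n_side = 8) {
  lat <- as.matrix(expand.grid(i = 1:n_side, j = 1:n_side, k = 1:n_side))
  set.seed(17)
  structure(list(centers = lat * 1.0, values = runif(nrow(lat), 0.1, 0.6),
                 size_mm = 1, lattice = lat), class = "scalar_mesh")
}
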