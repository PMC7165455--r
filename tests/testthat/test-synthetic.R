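test_that("head mask matches the analytic hemisphere volume", {
  # reference scale (radius 18 mm, voxel 0.3 mm): within 2%
  big <- fixture("big_mask", make_head_mask)
  zb <- voxel_coords(big, 3)
  hemi_big <- sum(big$voxels[, , zb >= 0])
  expect_lt(abs(hemi_big / ((2 / 3) * pi * 18^3 / 0.3^3) - 1), 0.02)
  # coarser test head (radius/voxel = 20): discretisation is larger
  mask <- small_mask()  # radius 9 mm, voxel 0.45 mm
  zc <- voxel_coords(mask, 3)
  hemi <- sum(mask$voxels[, , zc >= 0])
  expect_lt(abs(hemi / ((2 / 3) * pi * 9^3 / 0.45^3) - 1), 0.05)
  lab <- label_components(mask$voxels == 1L)
  expect_length(lab$sizes, 1L)
  # determinism: no randomness in mask construction
  expect_identical(mask$voxels, make_head_mask(9, 5, 4.5, 0.45)$voxels)
})

test_that("degenerate head geometry is rejected", {
  expect_error(make_head_mask(9, 5, 10, 0.45), "neck wider")
  expect_error(make_head_mask(9, 5, 4.5, 1), "voxel_mm")
  expect_error(make_head_mask(9, 5, 4.5, 10), "voxel_mm")
})

test_that("target field follows its closed form", {
  mask <- small_mask()
  # single blob: amplitude 0.3 on base 0.2 at a voxel-centre position
  blob <- list(dir = c(0, 0, 1), depth = 0.25, amplitude = 0.3,
               sigma_mm = 1.5)
  spec <- specimen_spec("human_one_pillar", head_radius_mm = 9,
                        voxel_mm = 0.45, base_bvtv = 0.2,
                        blobs = list(blob), neck_length_mm = 5,
                        neck_radius_mm = 4.5)
  tr <- target_field(spec, mask)
  ctr <- c(0, 0, 9 * 0.75)
  ci <- round((ctr - mask$origin_mm) / mask$voxel_mm) + 1
  expect_equal(tr$field[ci[1], ci[2], ci[3]], 0.5, tolerance = 1e-9)
  # >= 4 sigma away the blob contributes < 1e-3
  far <- abs(tr$field[ci[1], ci[2], ci[3] - round(4.5 * 1.5 / 0.45)] - 0.2)
  expect_lt(far, 1e-3)
  # maximum attained within one voxel of the blob centre
  am <- arrayInd(which.max(tr$field), dim(tr$field))
  expect_lte(max(abs(am - ci)), 1)
})

test_that("uniform pattern yields a constant field; blob placement errors", {
  mask <- small_mask()
  spec <- small_spec("uniform")
  tr <- target_field(spec, mask)
  vals <- tr$field[mask$voxels == 1L]
  expect_true(all(vals == spec$base_bvtv))
  bad <- specimen_spec("human_one_pillar", head_radius_mm = 9,
                       voxel_mm = 0.45,
                       blobs = list(list(dir = c(0, 0, -1), depth = -1,
                                         amplitude = 0.3, sigma_mm = 2)),
                       neck_length_mm = 5, neck_radius_mm = 4.5)
  expect_error(target_field(bad, mask), "outside the mask")
})

test_that("human-pattern field peaks in the posterosuperior-medial octant", {
  mask <- small_mask()
  tr <- target_field(small_spec("human_one_pillar"), mask)
  am <- arrayInd(which.max(tr$field), dim(tr$field))
  pos <- mask$origin_mm + (am - 1) * mask$voxel_mm
  expect_gt(pos[1], 0)  # medial
  expect_lt(pos[2], 0)  # posterior
  expect_gt(pos[3], 0)  # superior
})

test_that("spec invariants are enforced", {
  expect_error(specimen_spec("human_one_pillar", blobs = list()), "exactly 1")
  b <- small_blob(c(0, 0.7, 0.7))
  expect_error(specimen_spec("ape_two_pillar", blobs = list(b)), "exactly 2")
  b2 <- small_blob(c(0, 0.75, 0.75))  # ~6 degrees apart
  expect_error(specimen_spec("ape_two_pillar", blobs = list(b, b2)),
               "60 deg")
  expect_error(specimen_spec("uniform", blobs = list(b)), "no blobs")
})

test_that("synthesized trabeculae realize the target fill fraction", {
  box <- bone_volume(array(1L, c(128, 128, 128)), 0.3, kind = "binary",
                     outer_mask = array(TRUE, c(128, 128, 128)))
  spec <- specimen_spec("uniform", base_bvtv = 0.3, voxel_mm = 0.3)
  tr <- list(field = array(0.3, c(128, 128, 128)),
             blob_centers_mm = matrix(0, 0, 3), pattern = "uniform")
  class(tr) <- "ground_truth"
  vol <- synthesize_trabeculae(tr, box, 0.3, seed = 5)
  expect_gt(mean(vol$voxels), 0.28)
  expect_lt(mean(vol$voxels), 0.32)
  # the 0.02 floor produces almost no bone
  tr$field[] <- 0.02
  v2 <- synthesize_trabeculae(tr, box, 0.3, seed = 5)
  expect_lt(mean(v2$voxels), 0.05)
  # PRNG contract
  v3 <- synthesize_trabeculae(tr, box, 0.3, seed = 5)
  expect_identical(v2$voxels, v3$voxels)
  v4 <- synthesize_trabeculae(tr, box, 0.3, seed = 6)
  expect_gt(sum(v2$voxels != v4$voxels), 0)
})

test_that("constant-field fill recovers the target within Monte Carlo error", {
  n <- 48
  box <- bone_volume(array(1L, rep(n, 3)), 0.3, kind = "binary")
  for (p in c(0.1, 0.3, 0.5)) {
    tr <- structure(list(field = array(p, rep(n, 3)),
                         blob_centers_mm = matrix(0, 0, 3)),
                    class = "ground_truth")
    fills <- vapply(1:10, function(s)
      mean(synthesize_trabeculae(tr, box, 0.3, seed = s)$voxels), numeric(1))
    se <- sd(fills) / sqrt(length(fills))
    expect_lt(abs(mean(fills) - p), 3 * se + 0.005)
  }
})

test_that("cohorts are balanced, deterministic and jitter-controlled", {
  specs <- list(a = small_spec("human_one_pillar"),
                b = small_spec("ape_two_pillar"))
  coh <- make_cohort(3, specs, master_seed = 9)
  expect_length(coh, 6)
  expect_equal(table(vapply(coh, `[[`, character(1), "group")),
               table(rep(c("a", "b"), each = 3)), ignore_attr = TRUE)
  coh2 <- make_cohort(3, specs, master_seed = 9)
  expect_identical(lapply(coh, function(s) s$volume$voxels),
                   lapply(coh2, function(s) s$volume$voxels))
  # zero jitter: identical ground-truth fields within a group
  coh0 <- make_cohort(2, specs["a"], master_seed = 9, jitter_deg = 0,
                      jitter_rel = 0)
  expect_identical(coh0[[1]]$truth$field, coh0[[2]]$truth$field)
  expect_error(make_cohort(3, list(), master_seed = 1), "empty spec map")
})

test_that("sphere-sampled BV/TV at blob centres beats antipodal points", {
  # separability premise at the reference scale (18-mm head, sigma 4.5)
  mask <- fixture("big_mask", make_head_mask)
  hits <- 0L
  for (s in 1:10) {
    set.seed(s)
    spec <- specimen_spec("human_one_pillar", seed = s)
    tr <- target_field(spec, mask)
    vol <- synthesize_trabeculae(tr, mask, spec$texture_corr_mm, seed = s)
    ctr <- tr$blob_centers_mm[1, ]
    anti <- -ctr * c(1, 1, 0) + c(0, 0, ctr[3])  # antipodal in azimuth
    v <- sample_bvtv_sphere(vol, rbind(ctr, anti), 7.5)
    hits <- hits + (v[1] > v[2])
  }
  expect_gte(hits, 10 * 0.95)
})
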