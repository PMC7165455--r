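test_that("sphere-sampled BV/TV equals brute-force voxel counting", {
  set.seed(21)
  for (rep in 1:10) {
    arr <- array(as.integer(runif(32^3) < runif(1, 0.2, 0.6)), c(32, 32, 32))
    msk <- array(runif(32^3) < 0.9, c(32, 32, 32))
    vol <- bone_volume(arr, 0.5, origin_mm = runif(3, -1, 1),
                       kind = "binary", outer_mask = msk)
    ctr <- matrix(runif(3, 4, 12), 1)
    v <- sample_bvtv_sphere(vol, ctr, diameter_mm = 7.5)
    oracle <- bvtv_oracle(vol, ctr[1, ], 7.5)
    expect_identical(as.integer(attr(v, "n_bone")), oracle[1])
    expect_identical(as.integer(attr(v, "n_total")), oracle[2])
    expect_equal(as.numeric(v), oracle[1] / oracle[2])
  }
})

test_that("sphere sampling saturates and empties correctly", {
  arr1 <- array(1L, c(24, 24, 24))
  v1 <- bone_volume(arr1, 0.5, kind = "binary")
  expect_equal(as.numeric(sample_bvtv_sphere(v1, rbind(c(6, 6, 6)), 5)), 1)
  arr0 <- array(0L, c(24, 24, 24))
  v0 <- bone_volume(arr0, 0.5, kind = "binary",
                    outer_mask = array(TRUE, c(24, 24, 24)))
  expect_equal(as.numeric(sample_bvtv_sphere(v0, rbind(c(6, 6, 6)), 5)), 0)
  # sphere smaller than two voxels, and spheres off in space
  expect_error(sample_bvtv_sphere(v1, rbind(c(6, 6, 6)), 0.5), "diameter")
  expect_error(sample_bvtv_sphere(v1, rbind(c(500, 500, 500)), 5),
               "zero in-mask")
})

test_that("adding bone voxels inside the sphere never decreases BV/TV", {
  set.seed(31)
  arr <- array(as.integer(runif(24^3) < 0.3), c(24, 24, 24))
  vol <- bone_volume(arr, 0.5, kind = "binary")
  ctr <- rbind(c(6, 6, 6))
  v0 <- as.numeric(sample_bvtv_sphere(vol, ctr, 6))
  for (rep in 1:5) {
    empty <- which(vol$voxels == 0L)
    vol$voxels[sample(empty, 200)] <- 1L
    v1 <- as.numeric(sample_bvtv_sphere(vol, ctr, 6))
    expect_gte(v1, v0)
    v0 <- v1
  }
})

test_that("background grid nodes match brute-force lattice enumeration", {
  mask <- small_mask()
  grid <- seed_background_grid(mask, spacing_mm = 2.5)
  # independent enumeration over the image-anchored lattice
  m <- mask$voxels > 0
  cnt <- 0L
  for (gx in 0:20) for (gy in 0:20) for (gz in 0:20) {
    pos <- mask$origin_mm + c(gx, gy, gz) * 2.5
    if (any(pos > mask$origin_mm + (dim(m) - 1) * mask$voxel_mm)) next
    idx <- round((pos - mask$origin_mm) / mask$voxel_mm) + 1
    if (all(idx >= 1) && all(idx <= dim(m)) && m[idx[1], idx[2], idx[3]])
      cnt <- cnt + 1L
  }
  expect_equal(nrow(grid$nodes), cnt)
  # node order is lexicographic by z, y, x
  o <- order(grid$nodes[, 3], grid$nodes[, 2], grid$nodes[, 1])
  expect_identical(o, seq_len(nrow(grid$nodes)))
  expect_error(seed_background_grid(mask, spacing_mm = 100), "no nodes")
})

test_that("grid node count is invariant to translation by one period", {
  arr <- array(0L, c(30, 30, 30))
  arr[8:22, 8:22, 8:22] <- 1L
  v1 <- bone_volume(arr, 1, origin_mm = c(0, 0, 0), kind = "binary")
  v2 <- bone_volume(arr, 1, origin_mm = c(3.5, 0, 0), kind = "binary")
  g1 <- seed_background_grid(v1, 3.5)
  g2 <- seed_background_grid(v2, 3.5)
  expect_equal(nrow(g1$nodes), nrow(g2$nodes))
})

test_that("scalar-mesh interpolation reproduces constants and linear fields", {
  arr <- array(1L, c(41, 41, 41))
  box <- bone_volume(arr, 1, origin_mm = c(0, 0, 0), kind = "binary")
  grid <- seed_background_grid(box, 3.5)
  # constant
  grid$bvtv <- rep(0.4, nrow(grid$nodes)); grid$valid[] <- TRUE
  mesh <- build_scalar_mesh(box, grid, 1)
  expect_true(all(abs(mesh$values - 0.4) < 1e-12))
  # linear function, checked where cells are complete (interior)
  f <- function(p) 0.1 + 0.005 * p[, 1] + 0.003 * p[, 2] - 0.002 * p[, 3]
  grid$bvtv <- f(grid$nodes)
  mesh <- build_scalar_mesh(box, grid, 1)
  interior <- rowSums(mesh$centers > 4 & mesh$centers < 36) == 3
  expect_lt(max(abs(mesh$values[interior] - f(mesh$centers)[interior])),
            1e-9)
  # an invalid node is excluded but output stays finite
  grid$bvtv[1] <- NA
  mesh2 <- build_scalar_mesh(box, grid, 1)
  expect_true(all(is.finite(mesh2$values)))
  # all nodes invalid
  g0 <- grid; g0$valid[] <- FALSE
  expect_error(build_scalar_mesh(box, g0, 1), "4 valid")
})

test_that("percentile regions flag exactly the top share of tie-free fields", {
  # tie-free integer field 1..10000 on a 3D lattice
  lat <- as.matrix(expand.grid(i = 1:25, j = 1:25, k = 1:16))
  set.seed(8)
  vals <- sample(1:10000)
  mesh <- structure(list(centers = lat * 1.0, values = vals, size_mm = 1,
                         lattice = lat), class = "scalar_mesh")
  for (pct in c(75, 80, 85)) {
    rg <- percentile_regions(mesh, pct)
    expect_equal(sum(rg$above), round((100 - pct) / 100 * 10000))
  }
  rg <- percentile_regions(mesh, 80)
  expect_equal(sum(rg$above), 2000L)
  expect_equal(sum(rg$sizes), 2000L)
  # constant field: nothing above, with a warning
  mesh$values <- rep(1, nrow(lat))
  expect_warning(rg0 <- percentile_regions(mesh, 80), "degenerate")
  expect_equal(rg0$n_components, 0L)
  expect_equal(sum(rg0$above), 0L)
})

test_that("connected components of flagged regions are counted correctly", {
  # two separated hot blocks in a 10x10x3 slab
  lat <- as.matrix(expand.grid(i = 1:10, j = 1:10, k = 1:3))
  vals <- rep(0.2, nrow(lat))
  hot1 <- lat[, 1] <= 2 & lat[, 2] <= 2
  hot2 <- lat[, 1] >= 9 & lat[, 2] >= 9
  vals[hot1] <- 0.9; vals[hot2] <- 0.8
  vals <- vals + seq_len(nrow(lat)) * 1e-6  # break ties
  mesh <- structure(list(centers = lat * 1.0, values = vals, size_mm = 1,
                         lattice = lat), class = "scalar_mesh")
  rg <- percentile_regions(mesh, 92)
  expect_equal(rg$n_components_all, 2L)
  expect_equal(sort(rg$sizes), c(12L, 12L))
})

test_that("single specimens recover their pillar count", {
  cfg <- small_config()
  h <- small_volume("human_one_pillar", seed = 3)
  a <- small_volume("ape_two_pillar", seed = 3)
  mh <- map_specimen(h, cfg)
  ma <- map_specimen(a, cfg)
  expect_equal(mh$regions$n_components, 1L)
  expect_equal(ma$regions$n_components, 2L)
})
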