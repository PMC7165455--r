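test_that("binary volumes round-trip losslessly through NIfTI", {
  set.seed(42)
  arr <- array(as.integer(runif(64^3) < 0.3), c(64, 64, 64))
  vol <- bone_volume(arr, 0.3, c(-1, 2, 0.5), "binary")
  f <- tempfile(fileext = ".nii.gz")
  write_volume(vol, f)
  back <- read_volume(f)
  expect_identical(back$voxels, vol$voxels)
  expect_equal(back$voxel_mm, 0.3)
  expect_equal(back$origin_mm, c(-1, 2, 0.5))
  expect_equal(back$kind, "binary")
})

test_that("TIFF stack + sidecar reads identically to NIfTI of the same data", {
  set.seed(7)
  arr <- array(as.integer(runif(20^3) < 0.4), c(20, 20, 20))
  vol <- bone_volume(arr, 0.5, kind = "binary")
  f1 <- tempfile(fileext = ".nii")
  d2 <- tempfile("stack")
  write_volume(vol, f1)
  write_volume(vol, d2)
  a <- read_volume(f1); b <- read_volume(d2)
  expect_identical(a$voxels, b$voxels)
  expect_equal(a$voxel_mm, b$voxel_mm)
})

test_that("volumes without voxel-size metadata are rejected", {
  d <- tempfile("stack")
  dir.create(d)
  tiff::writeTIFF(matrix(0, 8, 8), file.path(d, "slice_0001.tif"))
  expect_error(read_volume(d), "sidecar")
  # anisotropic NIfTI without sidecar
  f <- tempfile(fileext = ".nii")
  img <- RNifti::asNifti(array(0L, c(8, 8, 8)))
  RNifti::pixdim(img) <- c(1, 1, 2)
  RNifti::writeNifti(img, f)
  expect_error(read_volume(f), "anisotropic")
})

test_that("reorientation restores rotated arrays bit-identically", {
  set.seed(1)
  arr <- array(as.integer(runif(10 * 12 * 14) < 0.5), c(10, 12, 14))
  vol <- bone_volume(arr, 1, kind = "binary")
  # the same object scanned rotated 90 degrees about z: array dim1 runs
  # along anatomical +y, dim2 along -x, so B[i,j,k] = A[n1+1-j, i, k]
  B <- aperm(arr, c(2, 1, 3))[, dim(arr)[1]:1, ]
  rot <- bone_volume(B, 1, origin_mm = c(dim(arr)[1] - 1, 0, 0),
                     kind = "binary", axes = c("+y", "-x", "+z"))
  canon <- reorient_canonical(rot)
  expect_identical(canon$voxels, arr)
  expect_equal(canon$origin_mm, c(0, 0, 0))
  expect_identical(reorient_canonical(canon)$voxels, arr)
})

test_that("reorient_resample preserves content and obeys contracts", {
  set.seed(3)
  arr <- array(as.integer(runif(40^3) < 0.35), c(40, 40, 40))
  vol <- bone_volume(arr, 0.5, kind = "binary")
  # identity
  same <- reorient_resample(vol)
  expect_identical(same$voxels, vol$voxels)
  # 2x downsample of a uniform-fill volume keeps the fill fraction
  down <- reorient_resample(vol, target_voxel_mm = 1)
  expect_lt(abs(mean(down$voxels) - mean(vol$voxels)), 0.01)
  expect_true(all(down$voxels %in% c(0L, 1L)))
  # empty crop box and bone-free crop are rejected
  expect_error(reorient_resample(vol, crop_box_mm = list(min = c(0, 0, 0),
                                                         max = c(0, 0, 0))),
               "empty crop box")
  empty <- bone_volume(array(0L, c(8, 8, 8)), 1, kind = "binary")
  empty$voxels[1, 1, 1] <- 1L
  expect_error(reorient_resample(empty,
                                 crop_box_mm = list(min = c(4, 4, 4),
                                                    max = c(7, 7, 7))),
               "excludes all bone")
})

test_that("Otsu segmentation separates a bimodal mixture", {
  set.seed(11)
  truth <- array(as.integer(runif(32^3) < 0.4), c(32, 32, 32))
  inten <- array(rnorm(32^3, mean = ifelse(truth == 1, 180, 60), sd = 20),
                 c(32, 32, 32))
  gray <- bone_volume(inten, 0.5, kind = "gray")
  seg <- segment_threshold(gray, "otsu")
  thr <- attr(seg, "threshold")
  expect_gt(thr, 60); expect_lt(thr, 180)
  expect_lt(mean(seg$voxels != truth), 0.02)
  # fixed threshold at the minimum marks everything as bone
  seg_all <- segment_threshold(gray, "fixed", threshold = min(inten))
  expect_true(all(seg_all$voxels == 1L))
  # constant volumes have no Otsu threshold
  flat <- bone_volume(array(5, c(8, 8, 8)), 1, kind = "gray")
  expect_error(segment_threshold(flat, "otsu"), "constant")
})

test_that("small-component cleanup removes speckle", {
  arr <- array(0L, c(20, 20, 20))
  arr[5:15, 5:15, 5:15] <- 1L   # big block
  arr[1, 1, 1] <- 1L            # speck
  gray <- bone_volume(array(as.numeric(arr), dim(arr)), 1, kind = "gray")
  seg <- segment_threshold(gray, "fixed", threshold = 0.5,
                           min_component_voxels = 5L)
  expect_equal(sum(seg$voxels), 11^3)
  lab <- label_components(seg$voxels == 1L)
  expect_length(lab$sizes, 1L)
})
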