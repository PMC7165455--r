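#' Read a volume from disk
#'
#' Supported formats: NIfTI (`.nii` / `.nii.gz`, read with RNifti) and a
#' directory containing a TIFF slice stack plus a `volume.json` sidecar.
#' A JSON sidecar (`<path>.json` for NIfTI) always takes precedence over
#' header metadata; without one, the NIfTI `pixdim` must be present,
#' positive and isotropic.  The volume is returned reoriented to the
#' canonical anatomical frame (+x medial, +y anterior, +z superior).
#'
#' @param path file (NIfTI) or directory (TIFF stack).
#' @return a `bone_volume`.
#' @export
read_volume <- function(path) {
  if (dir.exists(path)) return(read_tiff_stack(path))
  if (!file.exists(path)) stop("file not found: ", path)
  if (!grepl("\\.nii(\\.gz)?$", path)) stop("unsupported volume format: ", path)
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(meta)) {
    pd <- RNifti::pixdim(img)
    if (length(pd) < 3 || any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0))
      stop("voxel size missing from NIfTI header and no sidecar present")
    if (max(pd[1:3]) - min(pd[1:3]) > 1e-9 * max(pd[1:3]))
      stop("anisotropic voxels: resample to an isotropic grid first")
    meta <- list(voxel_mm = pd[1], origin_mm = c(0, 0, 0),
                 axes = c("+x", "+y", "+z"),
                 kind = if (all(arr %in% c(0, 1))) "binary" else "gray")
  }
  if (identical(meta$kind, "binary"))
    arr <- array(as.integer(round(arr)), dim(arr))
  om <- read_outer_mask(meta, dirname(path))
  vol <- bone_volume(arr, meta$voxel_mm, meta$origin_mm, meta$kind,
                     meta$axes, outer_mask = om)
  reorient_canonical(vol)
}

#' Write a volume to disk
#'
#' NIfTI (`.nii` / `.nii.gz`) with voxel size in the header, plus a JSON
#' sidecar (`<path>.json`) carrying the full metadata (voxel size, origin,
#' axis convention, kind, optional extras such as the generating seed);
#' or a TIFF slice stack when `path` has no NIfTI extension and is
#' treated as a directory.
#'
#' @param vol a `bone_volume`.
#' @param path output file (NIfTI) or directory (TIFF stack).
#' @param extra named list merged into the JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, extra = list()) {
  meta <- c(list(voxel_mm = vol$voxel_mm, origin_mm = vol$origin_mm,
                 axes = vol$axes, kind = vol$kind), extra)
  if (!is.null(vol$outer_mask)) {
    mask_file <- if (grepl("\\.nii(\\.gz)?$", path))
      sub("(\\.nii(\\.gz)?)$", "_mask\\1", path)
    else file.path(path, "outer_mask.nii.gz")
    meta$outer_mask_file <- basename(mask_file)
    mimg <- RNifti::asNifti(array(as.integer(vol$outer_mask),
                                  dim(vol$outer_mask)))
    RNifti::pixdim(mimg) <- rep(vol$voxel_mm, 3)
    if (!grepl("\\.nii(\\.gz)?$", path))
      dir.create(path, showWarnings = FALSE, recursive = TRUE)
    RNifti::writeNifti(mimg, mask_file)
  }
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(vol$voxels)
    RNifti::pixdim(img) <- rep(vol$voxel_mm, 3)
    RNifti::writeNifti(img, path)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    n3 <- dim(vol$voxels)[3]
    rng <- range(vol$voxels)
    scl <- if (diff(rng) > 0) diff(rng) else 1
    for (k in seq_len(n3)) {
      sl <- (vol$voxels[, , k] - rng[1]) / scl
      tiff::writeTIFF(t(sl), file.path(path, sprintf("slice_%04d.tif", k)),
                      bits.per.sample = 16L)
    }
    meta$intensity_range <- rng
    jsonlite::write_json(meta, file.path(path, "volume.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

read_tiff_stack <- function(path) {
  side <- file.path(path, "volume.json")
  if (!file.exists(side))
    stop("TIFF stack is missing its volume.json sidecar (voxel size unknown)")
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE))
  if (length(files) == 0) stop("no TIFF slices in ", path)
  slices <- lapply(files, function(f) t(tiff::readTIFF(f)))
  arr <- array(unlist(slices), c(dim(slices[[1]]), length(slices)))
  rng <- meta$intensity_range
  if (!is.null(rng) && diff(rng) > 0) arr <- arr * diff(rng) + rng[1]
  else if (!is.null(rng)) arr <- arr + rng[1]
  if (identical(meta$kind, "binary")) arr <- array(as.integer(round(arr)), dim(arr))
  om <- read_outer_mask(meta, path)
  reorient_canonical(
    bone_volume(arr, meta$voxel_mm, meta$origin_mm, meta$kind, meta$axes,
                outer_mask = om))
}

read_outer_mask <- function(meta, dir) {
  if (is.null(meta$outer_mask_file)) return(NULL)
  f <- file.path(dir, meta$outer_mask_file)
  if (!file.exists(f)) return(NULL)
  m <- RNifti::readNifti(f)
  array(as.numeric(m) > 0, dim(m))
}
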