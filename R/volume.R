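#' Volume containers
#'
#' A `bone_volume` wraps a 3D voxel array with its physical metadata:
#' isotropic voxel size (mm), the anatomical position of the first voxel
#' centre, and the anatomical direction each array dimension runs along.
#' The anatomical frame is +x medial, +y anterior, +z superior.
#'
#' `kind = "binary"` volumes hold strictly 0/1 voxels (1 = bone) and may
#' carry an `outer_mask`: the filled envelope (e.g. the subchondral /
#' periosteal boundary of the epiphysis) within which BV/TV is defined.
#'
#' @param voxels 3D numeric/integer/logical array.
#' @param voxel_mm isotropic voxel edge length in mm (> 0).
#' @param origin_mm anatomical coordinates (mm) of the centre of voxel
#'   `[1,1,1]`.
#' @param kind `"gray"` or `"binary"`.
#' @param axes length-3 character vector; `axes[d]` gives the signed
#'   anatomical axis (`"+x"`, `"-z"`, ...) along which array dimension
#'   `d` increases.  Canonical orientation is `c("+x","+y","+z")`.
#' @param outer_mask optional logical array of the same dimension (binary
#'   volumes only).
#' @return An object of class `bone_volume`.
#' @export
bone_volume <- function(voxels, voxel_mm, origin_mm = c(0, 0, 0),
                        kind = c("gray", "binary"),
                        axes = c("+x", "+y", "+z"),
                        outer_mask = NULL) {
  kind <- match.arg(kind)
  if (length(dim(voxels)) != 3L) stop("`voxels` must be a 3D array")
  if (!is.numeric(voxel_mm) || length(voxel_mm) != 1L || voxel_mm <= 0)
    stop("`voxel_mm` must be a single positive length")
  if (length(origin_mm) != 3L) stop("`origin_mm` must be a 3-vector")
  check_axes(axes)
  if (is.logical(voxels)) voxels <- array(as.integer(voxels), dim(voxels))
  if (kind == "binary") {
    u <- unique(as.vector(voxels))
    if (!all(u %in% c(0, 1)))
      stop("binary volume voxels must be strictly 0/1")
  }
  if (!is.null(outer_mask)) {
    if (!identical(dim(outer_mask), dim(voxels)))
      stop("`outer_mask` dimensions must match `voxels`")
    outer_mask <- array(as.logical(outer_mask), dim(outer_mask))
  }
  structure(
    list(voxels = voxels, voxel_mm = as.numeric(voxel_mm),
         origin_mm = as.numeric(origin_mm), kind = kind, axes = axes,
         outer_mask = outer_mask),
    class = "bone_volume")
}

check_axes <- function(axes) {
  ok <- is.character(axes) && length(axes) == 3L &&
    all(grepl("^[+-][xyz]$", axes)) &&
    length(unique(substr(axes, 2, 2))) == 3L
  if (!ok) stop("`axes` must name three distinct signed anatomical axes")
  invisible(axes)
}

#' @export
print.bone_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<bone_volume[%s]> %d x %d x %d voxels @ %.4g mm, axes (%s)\n",
              x$kind, d[1], d[2], d[3], x$voxel_mm,
              paste(x$axes, collapse = ",")))
  if (x$kind == "binary")
    cat(sprintf("  bone fraction %.4f%s\n", mean(x$voxels),
                if (!is.null(x$outer_mask)) " (outer mask present)" else ""))
  invisible(x)
}

#' Voxel-centre coordinates along one array dimension
#'
#' Only defined for volumes in canonical orientation.
#' @param vol a `bone_volume` in canonical orientation.
#' @param d array dimension (1, 2 or 3).
#' @return numeric vector of anatomical coordinates (mm).
#' @export
voxel_coords <- function(vol, d) {
  stopifnot(is_canonical(vol))
  vol$origin_mm[d] + (seq_len(dim(vol$voxels)[d]) - 1) * vol$voxel_mm
}

is_canonical <- function(vol) identical(vol$axes, c("+x", "+y", "+z"))

#' Reorient a volume to the canonical anatomical frame
#'
#' Permutes and flips the voxel array so that array dimensions 1,2,3 run
#' along +x (medial), +y (anterior), +z (superior), updating the origin
#' accordingly.  A no-op for canonical volumes.
#'
#' @param vol a `bone_volume`.
#' @return the reoriented `bone_volume` (voxel values bit-identical).
#' @export
reorient_canonical <- function(vol) {
  if (is_canonical(vol)) return(vol)
  letters3 <- substr(vol$axes, 2, 2)
  signs <- ifelse(substr(vol$axes, 1, 1) == "+", 1, -1)
  perm <- match(c("x", "y", "z"), letters3)  # perm[k]: array dim of axis k
  n <- dim(vol$voxels)
  flip_arr <- function(a) {
    a <- aperm(a, perm)
    idx <- lapply(1:3, function(k)
      if (signs[perm[k]] < 0) rev(seq_len(dim(a)[k])) else seq_len(dim(a)[k]))
    a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  }
  new_origin <- vapply(1:3, function(k) {
    d <- perm[k]
    if (signs[d] < 0) vol$origin_mm[k] - (n[d] - 1) * vol$voxel_mm
    else vol$origin_mm[k]
  }, numeric(1))
  # origin_mm components are already stored per anatomical axis
  bone_volume(flip_arr(vol$voxels), vol$voxel_mm, new_origin, vol$kind,
              c("+x", "+y", "+z"),
              if (!is.null(vol$outer_mask)) flip_arr(vol$outer_mask))
}

#' Reorient, crop and resample a volume
#'
#' Reorients to the canonical anatomical frame, optionally crops to an
#' axis-aligned box (mm) and resamples to a new isotropic voxel size.
#' Binary volumes are resampled by nearest neighbour so values stay
#' strictly 0/1; grayscale volumes use trilinear interpolation.
#'
#' @param vol a `bone_volume`.
#' @param target_voxel_mm new isotropic voxel size (mm); `NULL` keeps the
#'   current size.
#' @param crop_box_mm `NULL`, or `list(min = c(x,y,z), max = c(x,y,z))`
#'   in anatomical mm.
#' @return a canonical `bone_volume` covering the crop box.
#' @export
reorient_resample <- function(vol, target_voxel_mm = NULL,
                              crop_box_mm = NULL) {
  vol <- reorient_canonical(vol)
  if (is.null(target_voxel_mm)) target_voxel_mm <- vol$voxel_mm
  if (!is.numeric(target_voxel_mm) || target_voxel_mm <= 0)
    stop("`target_voxel_mm` must be positive")
  if (is.null(crop_box_mm)) {
    crop_box_mm <- list(
      min = vol$origin_mm - vol$voxel_mm / 2,
      max = vol$origin_mm + (dim(vol$voxels) - 1 + 0.5) * vol$voxel_mm)
  }
  lo <- as.numeric(crop_box_mm$min); hi <- as.numeric(crop_box_mm$max)
  if (any(hi <= lo)) stop("empty crop box")
  identity_grid <- isTRUE(all.equal(target_voxel_mm, vol$voxel_mm)) &&
    isTRUE(all.equal(lo, vol$origin_mm - vol$voxel_mm / 2)) &&
    isTRUE(all.equal(hi, vol$origin_mm +
                       (dim(vol$voxels) - 1 + 0.5) * vol$voxel_mm))
  if (identity_grid) return(vol)
  nnew <- pmax(1L, as.integer(round((hi - lo) / target_voxel_mm)))
  new_origin <- lo + target_voxel_mm / 2
  cc <- lapply(1:3, function(k) new_origin[k] +
                 (seq_len(nnew[k]) - 1) * target_voxel_mm)
  # source index (fractional) of each target coordinate
  fi <- lapply(1:3, function(k)
    (cc[[k]] - vol$origin_mm[k]) / vol$voxel_mm + 1)
  sample_nn <- function(a) {
    ii <- lapply(1:3, function(k) {
      r <- as.integer(round(fi[[k]]))
      r[r < 1L | r > dim(a)[k]] <- NA_integer_
      r
    })
    g <- as.matrix(expand.grid(i = ii[[1]], j = ii[[2]], k = ii[[3]]))
    out <- array(0, nnew)
    keep <- !is.na(g[, 1]) & !is.na(g[, 2]) & !is.na(g[, 3])
    out[keep] <- a[g[keep, , drop = FALSE]]
    out
  }
  if (vol$kind == "binary") {
    vox <- sample_nn(vol$voxels)
    if (sum(vox) == 0) stop("crop box excludes all bone voxels")
    om <- if (!is.null(vol$outer_mask)) sample_nn(vol$outer_mask) > 0
    bone_volume(vox, target_voxel_mm, new_origin, "binary",
                outer_mask = om)
  } else {
    vox <- trilinear_sample(vol$voxels, fi)
    bone_volume(vox, target_voxel_mm, new_origin, "gray")
  }
}

# trilinear interpolation of array `a` on the tensor grid of fractional
# indices fi (list of 3 vectors); out-of-range clamped to the edge
trilinear_sample <- function(a, fi) {
  n <- dim(a)
  f <- lapply(1:3, function(k) pmin(pmax(fi[[k]], 1), n[k]))
  i0 <- lapply(1:3, function(k) pmin(floor(f[[k]]), n[k] - 1))
  tt <- lapply(1:3, function(k) f[[k]] - i0[[k]])
  nn <- lengths(fi)
  out <- array(0, nn)
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    g <- as.matrix(expand.grid(i = i0[[1]] + dx, j = i0[[2]] + dy,
                               k = i0[[3]] + dz))
    w <- as.vector(outer(outer(
      if (dx) tt[[1]] else 1 - tt[[1]],
      if (dy) tt[[2]] else 1 - tt[[2]]),
      if (dz) tt[[3]] else 1 - tt[[3]]))
    out <- out + array(w * a[g], nn)
  }
  out
}
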