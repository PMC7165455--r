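#' Synthetic specimen specification
#'
#' Describes a synthetic femoral head: a hemispherical epiphysis with a
#' spatially varying target BV/TV field (baseline plus Gaussian
#' concentration blobs) and short-range trabecular texture.  The two
#' non-uniform patterns emulate the phenotypes of interest: a single
#' posterosuperior-medial concentration ("pillar") for the human-like
#' pattern and two separated anterior + posterior superior concentrations
#' for the ape-like pattern.
#'
#' Each blob is a list with elements `dir` (unit direction from the head
#' centre to the blob, anatomical frame), `depth` (fractional depth below
#' the surface along that direction, 0 = at the surface), `amplitude`
#' (added BV/TV at the blob centre), `sigma_mm` (Gaussian width), and
#' optionally `elong_axis` / `elong_factor` (distances along the axis are
#' divided by the factor, stretching the blob into a pillar).
#'
#' @param pattern `"human_one_pillar"`, `"ape_two_pillar"` or `"uniform"`.
#' @param head_radius_mm femoral head radius (mm).
#' @param voxel_mm isotropic voxel size (mm).
#' @param base_bvtv baseline bone volume fraction in `[0,1]`.
#' @param blobs list of blob descriptions; `NULL` installs the pattern's
#'   defaults.
#' @param texture_corr_mm correlation length of the trabecular texture.
#' @param neck_length_mm,neck_radius_mm neck stub geometry.
#' @param seed integer seed for texture synthesis.
#' @return a `specimen_spec`.
#' @export
specimen_spec <- function(pattern = c("human_one_pillar", "ape_two_pillar",
                                      "uniform"),
                          head_radius_mm = 18, voxel_mm = 0.3,
                          base_bvtv = 0.2, blobs = NULL,
                          texture_corr_mm = 0.3,
                          neck_length_mm = 10, neck_radius_mm = 9,
                          seed = 1L) {
  pattern <- match.arg(pattern)
  stopifnot(head_radius_mm > 0, voxel_mm > 0, base_bvtv >= 0, base_bvtv <= 1,
            texture_corr_mm > 0)
  if (is.null(blobs)) blobs <- default_blobs(pattern)
  nb <- length(blobs)
  if (pattern == "human_one_pillar" && nb != 1L)
    stop("human_one_pillar pattern requires exactly 1 blob")
  if (pattern == "ape_two_pillar") {
    if (nb != 2L) stop("ape_two_pillar pattern requires exactly 2 blobs")
    d1 <- unitize(blobs[[1]]$dir); d2 <- unitize(blobs[[2]]$dir)
    ang <- acos(pmin(1, pmax(-1, sum(d1 * d2)))) * 180 / pi
    if (ang < 60) stop("ape_two_pillar blob centres must be >= 60 deg apart")
  }
  if (pattern == "uniform" && nb != 0L)
    stop("uniform pattern takes no blobs")
  amps <- vapply(blobs, function(b) b$amplitude, numeric(1))
  if (base_bvtv + sum(pmax(amps, 0)) > 1 + 1e-12) {
    # the field is clipped to [0.02, 0.95] downstream, so this is legal,
    # but reject clearly unphysical requests
    if (base_bvtv + sum(pmax(amps, 0)) > 2)
      stop("base_bvtv plus blob amplitudes is unphysically large")
  }
  structure(list(pattern = pattern, head_radius_mm = head_radius_mm,
                 voxel_mm = voxel_mm, base_bvtv = base_bvtv, blobs = blobs,
                 texture_corr_mm = texture_corr_mm,
                 neck_length_mm = neck_length_mm,
                 neck_radius_mm = neck_radius_mm, seed = as.integer(seed)),
            class = "specimen_spec")
}

unitize <- function(v) v / sqrt(sum(v^2))

# Default blob geometry: human-like pattern concentrates bone
# posterosuperior-medially; ape-like anterior + posterior superiorly
# (90 deg apart).  Both are elongated along the superoinferior axis so
# the internal high-BV/TV regions form pillars.
default_blobs <- function(pattern) {
  mk <- function(dir) list(dir = unitize(dir), depth = 0.25,
                           amplitude = 0.35, sigma_mm = 4.5,
                           elong_axis = c(0, 0, 1), elong_factor = 2.5)
  switch(pattern,
         uniform = list(),
         human_one_pillar = list(mk(c(0.5, -0.5, 0.7))),
         ape_two_pillar = list(mk(c(0, 0.7, 0.7)), mk(c(0, -0.7, 0.7))))
}

#' Hemispherical head + neck stub mask
#'
#' The head is the upper (superior, z >= 0) hemisphere of the given
#' radius centred on the origin; a cylindrical neck stub of the given
#' radius extends inferiorly.  A voxel belongs to the mask when its
#' centre lies inside the solid.
#'
#' @param head_radius_mm head radius (mm).
#' @param neck_length_mm neck stub length (mm).
#' @param neck_radius_mm neck stub radius (mm, must be < head radius).
#' @param voxel_mm isotropic voxel size; must be <= head_radius_mm / 20.
#' @return a binary `bone_volume` (all-one inside the mask) whose
#'   `outer_mask` equals the mask itself.
#' @export
make_head_mask <- function(head_radius_mm = 18, neck_length_mm = 10,
                           neck_radius_mm = 9, voxel_mm = 0.3) {
  stopifnot(head_radius_mm > 0, neck_length_mm > 0, neck_radius_mm > 0,
            voxel_mm > 0)
  if (neck_radius_mm >= head_radius_mm)
    stop("degenerate geometry: neck wider than head")
  if (voxel_mm > head_radius_mm / 20)
    stop("voxel_mm must be <= head_radius_mm / 20")
  half <- ceiling(head_radius_mm / voxel_mm) + 1L
  zlo <- -(ceiling(neck_length_mm / voxel_mm) + 1L)
  xs <- (-half:half) * voxel_mm
  zs <- (zlo:half) * voxel_mm
  r2 <- outer(xs^2, xs^2, "+")
  head_r2 <- head_radius_mm^2
  neck_r2 <- neck_radius_mm^2
  arr <- array(0L, c(length(xs), length(xs), length(zs)))
  for (k in seq_along(zs)) {
    z <- zs[k]
    if (z >= 0) arr[, , k] <- (r2 + z^2 <= head_r2)
    else if (z >= -neck_length_mm) arr[, , k] <- (r2 <= neck_r2)
  }
  origin <- c(xs[1], xs[1], zs[1])
  bone_volume(arr, voxel_mm, origin, "binary", outer_mask = arr > 0)
}

#' Ground-truth target BV/TV field for a specimen
#'
#' field(x) = clip(base + sum_k amp_k exp(-d_k(x)^2 / (2 sigma_k^2)),
#' 0.02, 0.95), where d_k is the (optionally axis-elongated) distance to
#' blob centre k.  Blob centres are placed at
#' `dir * head_radius * (1 - depth)` and must fall inside the mask.
#'
#' @param spec a `specimen_spec`.
#' @param mask a binary `bone_volume` mask (from [make_head_mask()]).
#' @return a `ground_truth`: list with `field` (array, defined at every
#'   in-mask voxel, `NA` outside), `blob_centers_mm`, `pattern`.
#' @export
target_field <- function(spec, mask) {
  stopifnot(inherits(spec, "specimen_spec"), inherits(mask, "bone_volume"))
  m <- mask$voxels > 0
  n <- dim(m)
  xs <- voxel_coords(mask, 1); ys <- voxel_coords(mask, 2)
  zs <- voxel_coords(mask, 3)
  field <- array(spec$base_bvtv, n)
  centers <- matrix(0, length(spec$blobs), 3)
  for (bi in seq_along(spec$blobs)) {
    b <- spec$blobs[[bi]]
    ctr <- unitize(b$dir) * spec$head_radius_mm * (1 - b$depth)
    centers[bi, ] <- ctr
    ci <- round((ctr - mask$origin_mm) / mask$voxel_mm) + 1
    if (any(ci < 1) || any(ci > n) || !m[ci[1], ci[2], ci[3]])
      stop("blob centre falls outside the mask")
    dx <- xs - ctr[1]; dy <- ys - ctr[2]; dz <- zs - ctr[3]
    if (!is.null(b$elong_axis)) {
      ax <- unitize(b$elong_axis); ef <- b$elong_factor
      # d^2 = |perp|^2 + (par/ef)^2, computed separably
      # par = dx*ax1 + dy*ax2 + dz*ax3 (rank-1, use outer sums)
      par <- outer(outer(dx * ax[1], dy * ax[2], "+"), dz * ax[3], "+")
      full <- outer(outer(dx^2, dy^2, "+"), dz^2, "+")
      d2 <- full - par^2 + (par / ef)^2
    } else {
      d2 <- outer(outer(dx^2, dy^2, "+"), dz^2, "+")
    }
    field <- field + b$amplitude * exp(-d2 / (2 * b$sigma_mm^2))
  }
  field <- pmin(pmax(field, 0.02), 0.95)
  field <- array(field, n)
  field[!m] <- NA_real_
  structure(list(field = field, blob_centers_mm = centers,
                 pattern = spec$pattern, voxel_mm = mask$voxel_mm,
                 origin_mm = mask$origin_mm),
            class = "ground_truth")
}

#' Synthesize a binary trabecular volume realizing a target BV/TV field
#'
#' A stationary Gaussian random field with the requested correlation
#' length is thresholded pointwise at the normal quantile of the target
#' field, so the expected local fill fraction equals the target BV/TV
#' exactly: bone at x iff G(x) < qnorm(field(x)).
#'
#' @param truth a `ground_truth` (from [target_field()]).
#' @param mask the binary mask volume the truth was built on.
#' @param texture_corr_mm texture correlation length (mm); must be less
#'   than a quarter of the head radius.
#' @param seed integer PRNG seed.
#' @return a binary `bone_volume` with `outer_mask` set to the mask.
#' @export
synthesize_trabeculae <- function(truth, mask, texture_corr_mm = 0.3,
                                  seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  f <- truth$field
  m <- mask$voxels > 0
  if (any(!is.finite(f[m]))) stop("non-finite target field values")
  stopifnot(texture_corr_mm > 0)
  G <- gaussian_random_field(dim(f), sigma_vox = texture_corr_mm /
                               mask$voxel_mm, seed = seed)
  thr <- array(-Inf, dim(f))
  thr[m] <- qnorm(pmin(pmax(f[m], 1e-6), 1 - 1e-6))
  bone <- array(as.integer(m & (G < thr)), dim(f))
  bone_volume(bone, mask$voxel_mm, mask$origin_mm, "binary",
              outer_mask = m)
}

# smoothed, empirically standardized Gaussian random field via FFT
gaussian_random_field <- function(n, sigma_vox, seed) {
  set.seed(seed)
  w <- array(rnorm(prod(n)), n)
  if (sigma_vox > 0) {
    kern <- lapply(n, function(nk) {
      d <- pmin(0:(nk - 1), nk - (0:(nk - 1)))
      k <- exp(-d^2 / (2 * sigma_vox^2))
      k / sum(k)
    })
    K <- outer(outer(kern[[1]], kern[[2]]), kern[[3]])
    w <- Re(fft(fft(w) * fft(K), inverse = TRUE)) / prod(n)
  }
  (w - mean(w)) / sd(w)
}

#' Generate a cohort of synthetic specimens
#'
#' Per-specimen seeds are derived deterministically from `master_seed`;
#' within a group, blob centre directions are jittered by a small random
#' rotation (sd `jitter_deg` degrees) and blob amplitudes and widths by
#' independent relative Gaussian jitter (sd `jitter_rel`), emulating
#' individual variation around the group phenotype.
#'
#' @param n_per_group named integer vector or single integer (applied to
#'   every group in `specs_by_group`).
#' @param specs_by_group named list of `specimen_spec`s, one per group.
#' @param master_seed integer master seed.
#' @param jitter_deg sd of the angular jitter of blob directions.
#' @param jitter_rel relative sd of amplitude/width jitter.
#' @return list of specimens, each a list with `volume` (binary
#'   `bone_volume`), `truth` (`ground_truth`), `group`, `id`, `seed`.
#' @export
make_cohort <- function(n_per_group, specs_by_group, master_seed = 1L,
                        jitter_deg = 4, jitter_rel = 0.05) {
  if (length(specs_by_group) == 0L) stop("empty spec map")
  groups <- names(specs_by_group)
  if (is.null(groups)) stop("`specs_by_group` must be a named list")
  if (length(n_per_group) == 1L && is.null(names(n_per_group)))
    n_per_group <- setNames(rep(n_per_group, length(groups)), groups)
  stopifnot(all(n_per_group >= 1))
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max - 1L,
                      sum(unlist(n_per_group[groups])))
  sidx <- 0L
  out <- list()
  masks <- list()
  for (g in groups) {
    spec <- specs_by_group[[g]]
    geo_key <- paste(spec$head_radius_mm, spec$neck_length_mm,
                     spec$neck_radius_mm, spec$voxel_mm)
    if (is.null(masks[[geo_key]]))
      masks[[geo_key]] <- make_head_mask(spec$head_radius_mm,
                                         spec$neck_length_mm,
                                         spec$neck_radius_mm, spec$voxel_mm)
    mask <- masks[[geo_key]]
    for (i in seq_len(n_per_group[[g]])) {
      sidx <- sidx + 1L
      sseed <- seeds[sidx]
      set.seed(sseed)
      jspec <- spec
      jspec$blobs <- lapply(spec$blobs, function(b) {
        b$dir <- jitter_direction(unitize(b$dir), jitter_deg)
        b$amplitude <- b$amplitude * (1 + rnorm(1, 0, jitter_rel))
        b$sigma_mm <- b$sigma_mm * (1 + rnorm(1, 0, jitter_rel))
        b
      })
      truth <- target_field(jspec, mask)
      vol <- synthesize_trabeculae(truth, mask, spec$texture_corr_mm,
                                   seed = sseed)
      out[[length(out) + 1L]] <- list(
        volume = vol, truth = truth, group = g,
        id = sprintf("%s_%02d", g, i), seed = sseed)
    }
  }
  out
}

# rotate unit vector v by an angle ~ |N(0, sd_deg)| about a random
# perpendicular axis (no-op when sd_deg == 0)
jitter_direction <- function(v, sd_deg) {
  if (sd_deg == 0) return(v)
  ang <- rnorm(1, 0, sd_deg) * pi / 180
  seed_axis <- rnorm(3)
  ax <- seed_axis - v * sum(seed_axis * v)
  if (sum(ax^2) < 1e-12) return(v)
  ax <- unitize(ax)
  unitize(v * cos(ang) + ax * sin(ang))
}
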