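#' Seed the background sampling grid
#'
#' Places an axis-aligned lattice of the given spacing, anchored at the
#' volume's first voxel centre (image-anchored, so the grid follows the
#' scan), and keeps the nodes that fall inside the outer mask
#' (nearest-voxel membership).  Node order is deterministic:
#' lexicographic by z, then y, then x.
#'
#' @param mask a binary `bone_volume` whose `outer_mask` (or voxels)
#'   defines the sampling domain.
#' @param spacing_mm lattice spacing (default 3.5 mm).
#' @return a `background_grid`: list with `nodes` (n x 3 mm), `spacing_mm`,
#'   `bvtv` (NA until sampled), `valid` flags.
#' @export
seed_background_grid <- function(mask, spacing_mm = 3.5) {
  m <- mask_array(mask)
  if (!any(m)) stop("empty mask")
  n <- dim(m)
  rng <- lapply(1:3, function(d) range(voxel_coords(mask, d)))
  ax <- lapply(1:3, function(d)
    seq(rng[[d]][1], rng[[d]][2], by = spacing_mm))
  g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
  g <- g[order(g$z, g$y, g$x), , drop = FALSE]
  nodes <- as.matrix(g)
  idx <- round(sweep(nodes, 2, mask$origin_mm) / mask$voxel_mm) + 1
  inside <- idx[, 1] >= 1 & idx[, 1] <= n[1] &
    idx[, 2] >= 1 & idx[, 2] <= n[2] & idx[, 3] >= 1 & idx[, 3] <= n[3]
  inside[inside] <- m[idx[inside, , drop = FALSE]]
  nodes <- nodes[inside, , drop = FALSE]
  if (nrow(nodes) == 0L)
    stop("grid spacing larger than mask extent: no nodes")
  structure(list(nodes = unname(nodes), spacing_mm = spacing_mm,
                 anchor_mm = vapply(rng, `[`, numeric(1), 1),
                 bvtv = rep(NA_real_, nrow(nodes)),
                 valid = rep(TRUE, nrow(nodes))),
            class = "background_grid")
}

mask_array <- function(mask) {
  stopifnot(inherits(mask, "bone_volume"))
  if (!is.null(mask$outer_mask)) mask$outer_mask else mask$voxels > 0
}

#' Sphere-sampled BV/TV at a set of centres
#'
#' BV/TV at a centre is the number of bone voxels whose centre lies
#' within the sphere radius of the point (and inside the outer mask),
#' divided by the number of in-mask voxels within the radius.  When an
#' outer mask is present the denominator is restricted to it, so
#' near-surface values are not diluted by air outside the epiphysis;
#' without one the whole volume is the domain.
#'
#' @param bone a binary `bone_volume` with an `outer_mask`.
#' @param centers n x 3 matrix of sampling centres (mm).
#' @param diameter_mm sampling sphere diameter (default 7.5 mm).
#' @return numeric vector of BV/TV values in `[0,1]`; counts attached as
#'   attributes `"n_bone"` and `"n_total"`.
#' @export
sample_bvtv_sphere <- function(bone, centers, diameter_mm = 7.5) {
  stopifnot(inherits(bone, "bone_volume"), bone$kind == "binary")
  if (diameter_mm <= 2 * bone$voxel_mm)
    stop("sphere diameter must exceed two voxels")
  centers <- rbind(centers)
  # the sampling domain is the outer mask; without one, the whole volume
  m <- if (!is.null(bone$outer_mask)) bone$outer_mask
       else array(TRUE, dim(bone$voxels))
  b <- bone$voxels > 0 & m
  n <- dim(b)
  r <- diameter_mm / 2
  xs <- voxel_coords(bone, 1); ys <- voxel_coords(bone, 2)
  zs <- voxel_coords(bone, 3)
  nb <- nt <- integer(nrow(centers))
  for (i in seq_len(nrow(centers))) {
    ctr <- centers[i, ]
    ix <- which(abs(xs - ctr[1]) <= r)
    iy <- which(abs(ys - ctr[2]) <= r)
    iz <- which(abs(zs - ctr[3]) <= r)
    if (!length(ix) || !length(iy) || !length(iz)) {
      nt[i] <- 0L; next
    }
    d2 <- outer(outer((xs[ix] - ctr[1])^2, (ys[iy] - ctr[2])^2, "+"),
                (zs[iz] - ctr[3])^2, "+")
    inside <- d2 <= r^2
    msub <- m[ix, iy, iz, drop = FALSE]
    bsub <- b[ix, iy, iz, drop = FALSE]
    nt[i] <- sum(msub & inside)
    nb[i] <- sum(bsub & inside)
  }
  if (any(nt == 0L))
    stop("sampling sphere contains zero in-mask voxels at ",
         sum(nt == 0L), " centre(s)")
  out <- nb / nt
  attr(out, "n_bone") <- nb; attr(out, "n_total") <- nt
  out
}

#' Sample BV/TV at the nodes of a background grid
#'
#' Nodes whose sampling sphere is poorly covered by the mask (a thin
#' sliver at the specimen boundary) give high-variance BV/TV estimates;
#' they are sampled but marked invalid below `min_coverage` (fraction of
#' the full sphere's voxel count that lies inside the mask), so that the
#' scalar-mesh interpolation rests on stable nodes only.
#'
#' @param bone binary `bone_volume`.
#' @param grid a `background_grid`.
#' @param diameter_mm sampling sphere diameter (mm).
#' @param min_coverage minimum in-mask sphere coverage for a node to be
#'   marked valid.
#' @return the grid with `bvtv` and `valid` filled.
#' @export
sample_grid_bvtv <- function(bone, grid, diameter_mm = 7.5,
                             min_coverage = 0.25) {
  v <- sample_bvtv_sphere(bone, grid$nodes, diameter_mm)
  grid$bvtv <- as.numeric(v)
  full <- (4 / 3) * pi * (diameter_mm / 2)^3 / bone$voxel_mm^3
  grid$valid <- attr(v, "n_total") >= min_coverage * full
  grid
}

#' Build the BV/TV scalar element mesh
#'
#' Fills the mask interior with cubic elements of the requested edge
#' length (centres anchored at integer multiples of the mesh size) and
#' interpolates background-grid BV/TV onto each element centroid:
#' trilinear interpolation inside complete grid cells, inverse-distance
#' weighting (power 2, 8 nearest valid nodes) elsewhere.  Values never
#' overshoot the range of the contributing nodes.
#'
#' @param mask binary `bone_volume` defining the domain.
#' @param grid a sampled `background_grid`.
#' @param mesh_size_mm element edge length (default 1 mm).
#' @param interpolation `"linear"` (trilinear + IDW fallback) or `"idw"`.
#' @param zmin_mm optional floor on element-centre z: restricts the mesh
#'   to the epiphysis proper (e.g. 0 = above the head-neck plane),
#'   excluding any neck stub from the map.
#' @return a `scalar_mesh`: list with `centers` (n x 3), `values`,
#'   `size_mm`, `lattice` (integer lattice indices for adjacency).
#' @export
build_scalar_mesh <- function(mask, grid, mesh_size_mm = 1.0,
                              interpolation = c("linear", "idw"),
                              zmin_mm = NULL) {
  interpolation <- match.arg(interpolation)
  valid <- grid$valid & is.finite(grid$bvtv)
  if (sum(valid) < 4L) stop("need at least 4 valid grid nodes")
  nodes <- grid$nodes[valid, , drop = FALSE]
  vals <- grid$bvtv[valid]
  if (qr(sweep(nodes, 2, colMeans(nodes)))$rank < 3 && nrow(nodes) >= 4)
    stop("valid grid nodes are coplanar")
  m <- mask_array(mask)
  n <- dim(m)
  rng <- lapply(1:3, function(d) range(voxel_coords(mask, d)))
  ax <- lapply(1:3, function(d)
    seq(floor(rng[[d]][1] / mesh_size_mm),
        ceiling(rng[[d]][2] / mesh_size_mm)))
  g <- expand.grid(i = ax[[1]], j = ax[[2]], k = ax[[3]])
  g <- g[order(g$k, g$j, g$i), , drop = FALSE]
  lattice <- as.matrix(g)
  centers <- lattice * mesh_size_mm
  idx <- round(sweep(centers, 2, mask$origin_mm) / mask$voxel_mm) + 1
  inside <- idx[, 1] >= 1 & idx[, 1] <= n[1] &
    idx[, 2] >= 1 & idx[, 2] <= n[2] & idx[, 3] >= 1 & idx[, 3] <= n[3]
  inside[inside] <- m[idx[inside, , drop = FALSE]]
  if (!is.null(zmin_mm)) inside <- inside & centers[, 3] >= zmin_mm
  centers <- unname(centers[inside, , drop = FALSE])
  lattice <- unname(lattice[inside, , drop = FALSE])
  anchor <- if (!is.null(grid$anchor_mm)) grid$anchor_mm else c(0, 0, 0)
  values <- interp_grid(nodes, vals, grid$spacing_mm, anchor, centers,
                        force_idw = interpolation == "idw")
  structure(list(centers = centers, values = values,
                 size_mm = mesh_size_mm, lattice = lattice),
            class = "scalar_mesh")
}

#' @export
print.scalar_mesh <- function(x, ...) {
  cat(sprintf("<scalar_mesh> %d elements @ %.2g mm, BV/TV %.3f-%.3f (mean %.3f)\n",
              nrow(x$centers), x$size_mm, min(x$values), max(x$values),
              mean(x$values)))
  invisible(x)
}

# interpolate lattice node values at query points; nodes lie on a
# regular lattice (spacing_mm, anchored at anchor_mm)
interp_grid <- function(nodes, vals, spacing_mm, anchor_mm, query,
                        force_idw = FALSE) {
  key <- function(ijk) paste(ijk[, 1], ijk[, 2], ijk[, 3])
  nij <- round(sweep(nodes, 2, anchor_mm) / spacing_mm)
  lut <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(nij))) assign(key(nij[i, , drop = FALSE]), vals[i],
                                       envir = lut)
  out <- numeric(nrow(query))
  qrel <- sweep(query, 2, anchor_mm) / spacing_mm
  q0 <- floor(qrel)
  tt <- qrel - q0
  for (i in seq_len(nrow(query))) {
    got <- TRUE; acc <- 0; wmin <- Inf; wmax <- -Inf
    if (!force_idw) {
      for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
        k <- paste(q0[i, 1] + dx, q0[i, 2] + dy, q0[i, 3] + dz)
        v <- if (exists(k, envir = lut, inherits = FALSE))
          get(k, envir = lut) else NA_real_
        if (is.na(v)) { got <- FALSE; break }
        w <- (if (dx) tt[i, 1] else 1 - tt[i, 1]) *
          (if (dy) tt[i, 2] else 1 - tt[i, 2]) *
          (if (dz) tt[i, 3] else 1 - tt[i, 3])
        acc <- acc + w * v
        wmin <- min(wmin, v); wmax <- max(wmax, v)
      }
    } else got <- FALSE
    if (got) {
      out[i] <- min(max(acc, wmin), wmax)
    } else {
      d2 <- colSums((t(nodes) - query[i, ])^2)
      nn <- order(d2)[seq_len(min(8L, length(d2)))]
      if (d2[nn[1]] < 1e-18) { out[i] <- vals[nn[1]]; next }
      w <- 1 / d2[nn]  # power-2 IDW
      out[i] <- sum(w * vals[nn]) / sum(w)
    }
  }
  out
}

#' Percentile-thresholded internal regions of a scalar mesh
#'
#' Thresholds the per-element BV/TV at the given percentile (linear
#' interpolation quantile, matching R's default `quantile` type), flags
#' elements strictly above it, and labels 6-adjacent connected
#' components among flagged elements.
#'
#' @param mesh a `scalar_mesh`.
#' @param percentile percentile in (0, 100); the headline visualization
#'   uses 80 (the highest 20% of values), with 75 and 85 as companions.
#' @param min_component_elements components smaller than this are still
#'   labelled and listed in `sizes` but excluded from `n_components`
#'   (macroscopic-region count; 1 = count everything).
#' @return a `region_labels`: list with `percentile`, `threshold`,
#'   `above` (logical per element), `component` (integer per element, 0 =
#'   below threshold), `n_components` (components of at least
#'   `min_component_elements` elements), `n_components_all`, `sizes`.
#' @export
percentile_regions <- function(mesh, percentile = 80,
                               min_component_elements = 1L) {
  stopifnot(inherits(mesh, "scalar_mesh"), percentile > 0, percentile < 100)
  v <- mesh$values
  if (length(v) < 20L) stop("scalar mesh has fewer than 20 elements")
  thr <- as.numeric(quantile(v, percentile / 100, type = 7))
  above <- v > thr
  comp <- integer(length(v))
  if (!any(above)) {
    warning("constant or degenerate field: no elements above threshold")
    return(structure(list(percentile = percentile, threshold = thr,
                          above = above, component = comp,
                          n_components = 0L, n_components_all = 0L,
                          sizes = integer(0)),
                     class = "region_labels"))
  }
  sel <- which(above)
  lat <- mesh$lattice[sel, , drop = FALSE]
  kmap <- new.env(hash = TRUE, parent = emptyenv())
  keys <- paste(lat[, 1], lat[, 2], lat[, 3])
  for (i in seq_along(sel)) assign(keys[i], i, envir = kmap)
  edges <- NULL
  for (d in 1:3) {
    nb <- lat; nb[, d] <- nb[, d] + 1L
    nbk <- paste(nb[, 1], nb[, 2], nb[, 3])
    hit <- vapply(nbk, function(k) {
      if (exists(k, envir = kmap, inherits = FALSE))
        get(k, envir = kmap) else NA_integer_
    }, integer(1))
    has <- !is.na(hit)
    if (any(has)) edges <- rbind(edges, cbind(which(has), hit[has]))
  }
  g <- igraph::graph_from_edgelist(
    rbind(edges, cbind(seq_along(sel), seq_along(sel))), directed = FALSE)
  cc <- igraph::components(g)
  ord <- order(cc$csize, decreasing = TRUE)
  relabel <- integer(cc$no); relabel[ord] <- seq_len(cc$no)
  comp[sel] <- relabel[cc$membership]
  sizes <- as.integer(cc$csize[ord])
  structure(list(percentile = percentile, threshold = thr, above = above,
                 component = comp,
                 n_components = sum(sizes >= min_component_elements),
                 n_components_all = cc$no, sizes = sizes),
            class = "region_labels")
}
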