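#' Triangulated surface mesh
#'
#' @param vertices n x 3 matrix of vertex positions (mm).
#' @param faces m x 3 integer matrix of vertex indices (1-based).
#' @return a `surface_mesh` with per-vertex normals.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices); storage.mode(faces) <- "integer"
  m <- structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
  m$normals <- vertex_normals(m)
  # vertex -> incident-face adjacency, cached for fast projection
  fidx <- rep(seq_len(nrow(faces)), 3)
  vidx <- as.vector(faces)
  o <- order(vidx)
  m$vf_faces <- fidx[o]
  m$vf_start <- c(0L, cumsum(tabulate(vidx, nbins = nrow(vertices))))
  m$nn_index <- build_vertex_hash(vertices)
  m$face_normals <- face_normals(m)
  m
}

# uniform-grid spatial hash over mesh vertices for nearest-vertex queries
build_vertex_hash <- function(v, target_per_cell = 24) {
  n <- nrow(v)
  bbox <- apply(v, 2, range)
  vol <- prod(pmax(bbox[2, ] - bbox[1, ], 1e-9))
  h <- max((vol * target_per_cell / n)^(1 / 3), 1e-6)
  cell <- floor(sweep(v, 2, bbox[1, ]) / h)
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  buckets <- split(seq_len(n), key)
  env <- list2env(buckets, hash = TRUE, parent = emptyenv())
  list(h = h, origin = bbox[1, ], env = env)
}

# k nearest vertices for each row of p using the hash (exact: expands the
# search ring until the k-th best cannot be beaten)
nearest_vertices <- function(mesh, p, k = 3L) {
  v <- mesh$vertices
  idx <- mesh$nn_index
  if (is.null(idx)) idx <- build_vertex_hash(v)
  h <- idx$h; env <- idx$env; orig <- idx$origin
  np <- nrow(p)
  out <- matrix(0L, np, k)
  for (i in seq_len(np)) {
    c0 <- floor((p[i, ] - orig) / h)
    ring <- 1L
    repeat {
      cand <- integer(0)
      for (dx in -ring:ring) for (dy in -ring:ring) for (dz in -ring:ring) {
        kk <- paste(c0[1] + dx, c0[2] + dy, c0[3] + dz)
        b <- env[[kk]]
        if (!is.null(b)) cand <- c(cand, b)
      }
      if (length(cand) >= k) {
        d2 <- colSums((t(v[cand, , drop = FALSE]) - p[i, ])^2)
        o <- order(d2)[seq_len(min(k, length(d2)))]
        # safe if the k-th distance fits inside the searched ring
        if (sqrt(d2[o[length(o)]]) <= ring * h || ring > 64L) {
          out[i, seq_along(o)] <- cand[o]
          break
        }
      }
      ring <- ring + 1L
      if (ring > 128L) stop("nearest-vertex search failed to converge")
    }
  }
  out
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces, area %.2f mm^2\n",
              nrow(x$vertices), nrow(x$faces), mesh_area(x)))
  invisible(x)
}

face_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

vertex_normals <- function(mesh) {
  fn <- face_normals(mesh)  # area-weighted
  nv <- nrow(mesh$vertices)
  idx <- as.vector(mesh$faces)
  out <- matrix(0, nv, 3)
  for (d in 1:3) {
    s <- rowsum(rep(fn[, d], 3), idx)
    out[as.integer(rownames(s)), d] <- s
  }
  len <- sqrt(rowSums(out^2)); len[len == 0] <- 1
  out / len
}

#' Total surface area of a mesh (mm^2)
#' @param mesh a `surface_mesh`.
#' @export
mesh_area <- function(mesh) sum(sqrt(rowSums(face_normals(mesh)^2))) / 2

#' Volume enclosed by a (closed, consistently oriented) mesh (mm^3)
#' @param mesh a `surface_mesh`.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]; b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  abs(sum(a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
          a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
          a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1]))) / 6
}

# 6-tetrahedra decomposition of the unit cube around the 0-7 diagonal;
# cube corner c has offsets (bit0, bit1, bit2) along (x, y, z)
.tet_table <- matrix(c(0, 1, 5, 7,  0, 5, 4, 7,  0, 4, 6, 7,
                       0, 6, 2, 7,  0, 2, 3, 7,  0, 3, 1, 7),
                     ncol = 4, byrow = TRUE)

#' Isosurface of a binary volume by marching tetrahedra
#'
#' Each grid cell is split into six tetrahedra sharing the cell diagonal
#' (a decomposition consistent across neighbouring cells, so the surface
#' is watertight); surface vertices sit at midpoints of cell edges whose
#' endpoints differ in phase.  Faces are oriented outward (bone inside).
#'
#' @param mask logical/0-1 3D array.
#' @param voxel_mm voxel size (mm).
#' @param origin_mm position of voxel `[1,1,1]` centre.
#' @return a `surface_mesh`.
#' @export
marching_tetrahedra <- function(mask, voxel_mm = 1, origin_mm = c(0, 0, 0)) {
  f <- array(as.integer(mask), dim(mask))
  n <- dim(f); nx <- n[1]; ny <- n[2]; nz <- n[3]
  if (any(n < 2)) stop("volume too small for isosurfacing")
  lin <- array(seq_len(prod(n)), n)
  lin0 <- as.vector(lin[1:(nx - 1), 1:(ny - 1), 1:(nz - 1)])
  off <- integer(8)
  for (c in 0:7)
    off[c + 1] <- bitwAnd(c, 1L) + nx * bitwAnd(bitwShiftR(c, 1L), 1L) +
      nx * ny * bitwAnd(bitwShiftR(c, 2L), 1L)
  s <- integer(length(lin0))
  for (c in 1:8) s <- s + f[lin0 + off[c]]
  lin0 <- lin0[s > 0L & s < 8L]
  if (length(lin0) == 0L) stop("empty mask: no isosurface")

  tri_e1 <- tri_e2 <- tri_e3 <- vector("list", 0)
  tri_in <- tri_out <- vector("list", 0)
  push <- function(ea, eb, ec, pin, pout) {
    tri_e1[[length(tri_e1) + 1]] <<- ea
    tri_e2[[length(tri_e2) + 1]] <<- eb
    tri_e3[[length(tri_e3) + 1]] <<- ec
    tri_in[[length(tri_in) + 1]] <<- pin
    tri_out[[length(tri_out) + 1]] <<- pout
  }
  ekey <- function(a, b) {
    lo <- pmin(a, b); hi <- pmax(a, b)
    as.numeric(lo) * (prod(n) + 1) + as.numeric(hi)
  }
  for (t in 1:6) {
    corn <- .tet_table[t, ]
    A <- cbind(lin0 + off[corn[1] + 1], lin0 + off[corn[2] + 1],
               lin0 + off[corn[3] + 1], lin0 + off[corn[4] + 1])
    V <- cbind(f[A[, 1]], f[A[, 2]], f[A[, 3]], f[A[, 4]])
    cid <- V[, 1] + 2L * V[, 2] + 4L * V[, 3] + 8L * V[, 4]
    for (case in 1:14) {
      rows <- which(cid == case)
      if (!length(rows)) next
      ins <- which(bitwAnd(case, c(1L, 2L, 4L, 8L)) > 0L)
      outs <- setdiff(1:4, ins)
      Ai <- A[rows, , drop = FALSE]
      if (length(ins) == 1L || length(ins) == 3L) {
        a <- if (length(ins) == 1L) ins else outs
        oth <- setdiff(1:4, a)
        push(ekey(Ai[, a], Ai[, oth[1]]),
             ekey(Ai[, a], Ai[, oth[2]]),
             ekey(Ai[, a], Ai[, oth[3]]),
             if (length(ins) == 1L) Ai[, a] else Ai[, oth[1]],
             if (length(ins) == 1L) Ai[, oth[1]] else Ai[, a])
      } else {  # 2 in / 2 out: quad -> two triangles
        i1 <- ins[1]; i2 <- ins[2]; o1 <- outs[1]; o2 <- outs[2]
        e11 <- ekey(Ai[, i1], Ai[, o1]); e12 <- ekey(Ai[, i1], Ai[, o2])
        e22 <- ekey(Ai[, i2], Ai[, o2]); e21 <- ekey(Ai[, i2], Ai[, o1])
        push(e11, e12, e22, Ai[, i1], Ai[, o1])
        push(e11, e22, e21, Ai[, i1], Ai[, o1])
      }
    }
  }
  E1 <- unlist(tri_e1); E2 <- unlist(tri_e2); E3 <- unlist(tri_e3)
  Pin <- unlist(tri_in); Pout <- unlist(tri_out)
  keys <- c(E1, E2, E3)
  uk <- unique(keys)
  tri <- matrix(match(keys, uk), ncol = 3)
  # decode edge endpoints from key
  hi <- uk %% (prod(n) + 1); lo <- (uk - hi) / (prod(n) + 1)
  cpos <- function(idx) {
    ai <- arrayInd(as.integer(idx), n)
    sweep((ai - 1) * voxel_mm, 2, origin_mm, "+")
  }
  verts <- (cpos(lo) + cpos(hi)) / 2
  # outward orientation: flip faces whose normal points toward the bone
  p1 <- verts[tri[, 1], , drop = FALSE]
  e1 <- verts[tri[, 2], , drop = FALSE] - p1
  e2 <- verts[tri[, 3], , drop = FALSE] - p1
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  dirv <- cpos(Pout) - cpos(Pin)
  flip <- rowSums(nrm * dirv) < 0
  tmp <- tri[flip, 2]; tri[flip, 2] <- tri[flip, 3]; tri[flip, 3] <- tmp
  surface_mesh(verts, tri)
}

#' Taubin mesh smoothing
#'
#' Alternating shrink/inflate Laplacian passes (lambda then mu), which
#' smooths the voxelisation staircase while approximately preserving the
#' enclosed volume.
#'
#' @param mesh a `surface_mesh`.
#' @param iterations number of lambda/mu pass pairs.
#' @param lambda,mu Taubin coefficients (`mu < -lambda` inflates back).
#' @return the smoothed `surface_mesh`.
#' @export
taubin_smooth <- function(mesh, iterations = 30L, lambda = 0.5, mu = -0.53) {
  if (iterations <= 0L) return(mesh)
  f <- mesh$faces
  ed <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  ed <- cbind(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  ed <- unique(ed)
  nv <- nrow(mesh$vertices)
  W <- Matrix::sparseMatrix(i = c(ed[, 1], ed[, 2]), j = c(ed[, 2], ed[, 1]),
                            x = 1, dims = c(nv, nv))
  deg <- Matrix::rowSums(W); deg[deg == 0] <- 1
  W <- W / deg
  P <- mesh$vertices
  for (it in seq_len(iterations)) {
    P <- P + lambda * (as.matrix(W %*% P) - P)
    P <- P + mu * (as.matrix(W %*% P) - P)
  }
  surface_mesh(P, mesh$faces)
}

#' Extract the subchondral (outer-envelope) surface of a binary mask
#'
#' Isosurfaces the mask by marching tetrahedra and applies Taubin
#' smoothing.  The mask must be non-empty and 6-connected as a single
#' component; the extracted surface keeps its largest connected patch
#' (closed solid masks yield exactly one).
#'
#' @param mask a binary `bone_volume` (the filled envelope, not the
#'   porous trabecular structure) or a logical array.
#' @param smoothing_iters Taubin iteration pairs (0 = raw isosurface).
#' @param voxel_mm,origin_mm used when `mask` is a bare array.
#' @return a `surface_mesh`.
#' @export
extract_subchondral_surface <- function(mask, smoothing_iters = 30L,
                                        voxel_mm = 1, origin_mm = c(0, 0, 0)) {
  if (inherits(mask, "bone_volume")) {
    arr <- mask$voxels > 0; voxel_mm <- mask$voxel_mm; origin_mm <- mask$origin_mm
  } else arr <- mask > 0
  if (!any(arr)) stop("empty mask")
  lab <- label_components(arr)
  if (length(lab$sizes) > 1L)
    stop(sprintf("mask has %d connected components; expected 1",
                 length(lab$sizes)))
  mesh <- marching_tetrahedra(arr, voxel_mm, origin_mm)
  mesh <- keep_largest_patch(mesh)
  taubin_smooth(mesh, smoothing_iters)
}

keep_largest_patch <- function(mesh) {
  f <- mesh$faces
  g <- igraph::graph_from_edgelist(
    rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)],
          cbind(seq_len(nrow(mesh$vertices)), seq_len(nrow(mesh$vertices)))),
    directed = FALSE)
  comp <- igraph::components(g)
  if (comp$no == 1L) return(mesh)
  big <- which.max(comp$csize)
  keepv <- comp$membership == big
  remap <- cumsum(keepv)
  keepf <- keepv[f[, 1]] & keepv[f[, 2]] & keepv[f[, 3]]
  surface_mesh(mesh$vertices[keepv, , drop = FALSE],
               matrix(remap[f[keepf, ]], ncol = 3))
}

# ---- projection handles -------------------------------------------------

#' Analytic (hemi)sphere surface handle
#'
#' @param center sphere centre (mm).
#' @param radius sphere radius (mm).
#' @return a `surface_sphere` object usable wherever a surface handle is
#'   expected (exact projections; used for templates and tests).
#' @export
surface_sphere <- function(center = c(0, 0, 0), radius = 1) {
  structure(list(center = center, radius = radius), class = "surface_sphere")
}

#' Circle handle for a head-neck boundary rim
#'
#' @param center circle centre (mm).
#' @param radius circle radius (mm).
#' @param axis unit normal of the circle's plane.
#' @export
surface_circle <- function(center = c(0, 0, 0), radius = 1,
                           axis = c(0, 0, 1)) {
  structure(list(center = center, radius = radius,
                 axis = axis / sqrt(sum(axis^2))), class = "surface_circle")
}

#' Project points onto a surface handle
#'
#' @param surface a `surface_mesh`, `surface_sphere` or `surface_circle`.
#' @param p n x 3 matrix of query points.
#' @return list with `points` (n x 3 projected positions) and `normals`
#'   (n x 3 surface normals at them; for circles, the in-plane tangent is
#'   returned in `tangents` instead).
#' @export
project_to_surface <- function(surface, p) UseMethod("project_to_surface")

#' @export
project_to_surface.surface_sphere <- function(surface, p) {
  p <- rbind(p)
  d <- sweep(p, 2, surface$center)
  len <- sqrt(rowSums(d^2)); len[len == 0] <- 1
  nrm <- d / len
  list(points = sweep(nrm * surface$radius, 2, surface$center, "+"),
       normals = nrm)
}

#' @export
project_to_surface.surface_circle <- function(surface, p) {
  p <- rbind(p)
  d <- sweep(p, 2, surface$center)
  ax <- surface$axis
  par <- drop(d %*% ax)
  rad <- d - outer(par, ax)
  len <- sqrt(rowSums(rad^2)); len[len == 0] <- 1
  raddir <- rad / len
  pts <- sweep(raddir * surface$radius, 2, surface$center, "+")
  tang <- cbind(ax[2] * raddir[, 3] - ax[3] * raddir[, 2],
                ax[3] * raddir[, 1] - ax[1] * raddir[, 3],
                ax[1] * raddir[, 2] - ax[2] * raddir[, 1])
  list(points = pts, normals = raddir, tangents = tang)
}

#' @export
project_to_surface.surface_mesh <- function(surface, p) {
  p <- rbind(p)
  np <- nrow(p)
  v <- surface$vertices; f <- surface$faces
  fn <- if (!is.null(surface$face_normals)) surface$face_normals
        else face_normals(surface)
  nn <- nearest_vertices(surface, p, k = 3L)
  # candidate faces: all faces incident to the 3 nearest vertices
  vfF <- surface$vf_faces; vfS <- surface$vf_start
  if (is.null(vfF)) {  # meshes built by hand without the cache
    fidx <- rep(seq_len(nrow(f)), 3); vidx <- as.vector(f)
    o <- order(vidx); vfF <- fidx[o]
    vfS <- c(0L, cumsum(tabulate(vidx, nbins = nrow(v))))
  }
  vs <- as.vector(t(nn))
  cnt <- vfS[vs + 1L] - vfS[vs]
  pair_p <- rep(rep(seq_len(np), each = 3), cnt)
  pair_f <- vfF[sequence(cnt, from = vfS[vs] + 1L)]
  Q <- p[pair_p, , drop = FALSE]
  A <- v[f[pair_f, 1], , drop = FALSE]
  B <- v[f[pair_f, 2], , drop = FALSE]
  C <- v[f[pair_f, 3], , drop = FALSE]
  CP <- closest_point_triangle_vec(Q, A, B, C)
  d2 <- rowSums((CP - Q)^2)
  # argmin per query point
  o <- order(pair_p, d2)
  first <- o[!duplicated(pair_p[o])]
  out_p <- CP[first, , drop = FALSE]
  bf <- pair_f[first]
  nrm <- fn[bf, , drop = FALSE]
  nl <- sqrt(rowSums(nrm^2)); nl[nl == 0] <- 1
  list(points = out_p, normals = nrm / nl)
}

# closest points on triangles (A,B,C) to points P, all n x 3
# (vectorized form of Ericson, Real-Time Collision Detection, 5.1.5)
closest_point_triangle_vec <- function(p, a, b, c) {
  rs <- function(x, y) rowSums(x * y)
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- rs(ab, ap); d2 <- rs(ac, ap)
  bp <- p - b; d3 <- rs(ab, bp); d4 <- rs(ac, bp)
  cp <- p - c; d5 <- rs(ab, cp); d6 <- rs(ac, cp)
  vc <- d1 * d4 - d3 * d2
  vb <- d5 * d2 - d1 * d6
  va <- d3 * d6 - d5 * d4
  denom <- va + vb + vc; denom[denom == 0] <- 1
  vpar <- vb / denom; wpar <- vc / denom
  res <- a + ab * vpar + ac * wpar            # interior (default)
  m6 <- va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
  if (any(m6)) {
    t6 <- (d4 - d3) / pmax((d4 - d3) + (d5 - d6), 1e-300)
    res[m6, ] <- b[m6, , drop = FALSE] +
      (c - b)[m6, , drop = FALSE] * t6[m6]
  }
  m5 <- vb <= 0 & d2 >= 0 & d6 <= 0
  if (any(m5)) {
    t5 <- d2 / pmax(d2 - d6, 1e-300)
    res[m5, ] <- a[m5, , drop = FALSE] + ac[m5, , drop = FALSE] * t5[m5]
  }
  m4 <- d6 >= 0 & d5 <= d6
  if (any(m4)) res[m4, ] <- c[m4, , drop = FALSE]
  m3 <- vc <= 0 & d1 >= 0 & d3 <= 0
  if (any(m3)) {
    t3 <- d1 / pmax(d1 - d3, 1e-300)
    res[m3, ] <- a[m3, , drop = FALSE] + ab[m3, , drop = FALSE] * t3[m3]
  }
  m2 <- d3 >= 0 & d4 <= d3
  if (any(m2)) res[m2, ] <- b[m2, , drop = FALSE]
  m1 <- d1 <= 0 & d2 <= 0
  if (any(m1)) res[m1, ] <- a[m1, , drop = FALSE]
  res
}
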