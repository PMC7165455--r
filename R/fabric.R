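#' Quasi-uniform direction set from octahedron subdivision
#'
#' Recursively subdivides the regular octahedron and projects vertices to
#' the unit sphere; one direction per antipodal pair is kept.  Level 3
#' gives 129 unique directions.  The set is closed under the octahedral
#' symmetry group (axis permutations and sign flips), which keeps the
#' fabric fit well-conditioned and near-equivariant under 90-degree
#' volume rotations.
#'
#' @param level subdivision level (>= 0).
#' @return n x 3 matrix of unit directions, deterministic order.
#' @export
octahedron_directions <- function(level = 3L) {
  v <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
             c(0, 0, 1), c(0, 0, -1))
  f <- rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
             c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  for (l in seq_len(level)) {
    nv <- nrow(v); key <- new.env(hash = TRUE, parent = emptyenv())
    newv <- list(); nf <- list()
    mid <- function(a, b) {
      k <- paste(min(a, b), max(a, b))
      if (exists(k, envir = key, inherits = FALSE))
        return(get(k, envir = key))
      p <- v[a, ] + v[b, ]; p <- p / sqrt(sum(p^2))
      newv[[length(newv) + 1L]] <<- p
      id <- nv + length(newv)
      assign(k, id, envir = key)
      id
    }
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
      ab <- mid(a, b); bc <- mid(b, c); ca <- mid(c, a)
      nf[[length(nf) + 1L]] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                     c(c, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- do.call(rbind, nf)
  }
  # one representative per antipodal pair: keep z>0, then y>0, then x>0
  keep <- v[, 3] > 1e-12 |
    (abs(v[, 3]) <= 1e-12 & v[, 2] > 1e-12) |
    (abs(v[, 3]) <= 1e-12 & abs(v[, 2]) <= 1e-12 & v[, 1] > 0)
  u <- v[keep, , drop = FALSE]
  u[order(round(u[, 3], 12), round(u[, 2], 12), round(u[, 1], 12)), ,
    drop = FALSE]
}

#' Mean-intercept-length fabric tensor and degree of anisotropy
#'
#' Traces parallel test lines through the region along each direction,
#' counts bone/background phase changes (intercepts), and computes
#' MIL(v) = total in-region line length / intercept count.  An ellipsoid
#' is fitted by least squares to MIL(v)^-2 = v' H v; the fabric
#' semi-axes are 1/sqrt(eigenvalues of H) and DA = 1 - shortest/longest.
#'
#' @param bone binary `bone_volume` (or 0/1 array with `voxel_mm`).
#' @param region optional logical array (same dims) restricting the
#'   analysis; default: everything.
#' @param directions matrix of unit directions
#'   (default [octahedron_directions()] level 3: 129 directions).
#' @param line_spacing_vox spacing between parallel test lines (voxels).
#' @param voxel_mm voxel size when `bone` is a bare array.
#' @return a `fabric_result`: list with `eigenvalues` (semi-axes, sorted
#'   decreasing), `eigenvectors` (columns, matching order), `DA`, `mil`
#'   (per direction), `directions`.
#' @export
mean_intercept_length_DA <- function(bone, region = NULL,
                                     directions = octahedron_directions(3L),
                                     line_spacing_vox = 1L, voxel_mm = NULL) {
  if (inherits(bone, "bone_volume")) {
    arr <- bone$voxels > 0; voxel_mm <- bone$voxel_mm
  } else { arr <- bone > 0; if (is.null(voxel_mm)) voxel_mm <- 1 }
  n <- dim(arr)
  if (is.null(region)) region <- array(TRUE, n)
  stopifnot(identical(dim(region), n))
  nbone <- sum(arr & region); ntot <- sum(region)
  if (nbone == 0L || nbone == ntot)
    stop("region must contain both bone and background voxels")
  av <- array(as.integer(arr), n)
  rg <- array(region, n)
  mil <- numeric(nrow(directions))
  for (di in seq_len(nrow(directions))) {
    v <- directions[di, ]
    a <- which.max(abs(v))
    if (v[a] < 0) v <- -v
    bc <- setdiff(1:3, a)
    sb <- v[bc[1]] / v[a]; sc <- v[bc[2]] / v[a]
    na <- n[a]; nb <- n[bc[1]]; nc <- n[bc[2]]
    t <- 0:(na - 1)
    lo_b <- floor(1 - max(0, sb * (na - 1)))
    hi_b <- ceiling(nb - min(0, sb * (na - 1)))
    lo_c <- floor(1 - max(0, sc * (na - 1)))
    hi_c <- ceiling(nc - min(0, sc * (na - 1)))
    ob <- seq(lo_b, hi_b, by = line_spacing_vox)
    oc <- seq(lo_c, hi_c, by = line_spacing_vox)
    no <- length(ob) * length(oc)
    Ob <- rep(ob, times = length(oc))
    Oc <- rep(oc, each = length(ob))
    # index matrices (lines x steps)
    ib <- round(outer(Ob, t * sb, "+"))
    ic <- round(outer(Oc, t * sc, "+"))
    ia <- matrix(rep(t + 1, each = no), no, na)
    ok <- ib >= 1 & ib <= nb & ic >= 1 & ic <= nc
    idx <- matrix(1L, no, na)
    dims <- integer(3); dims[a] <- 1L; dims[bc[1]] <- 2L; dims[bc[2]] <- 3L
    mult <- cumprod(c(1, n[-3]))
    lin <- 1 + (ia - 1) * mult[a] + (ib - 1) * mult[bc[1]] +
      (ic - 1) * mult[bc[2]]
    lin[!ok] <- 1L
    vals <- matrix(av[lin], no, na); vals[!ok] <- NA_integer_
    inreg <- matrix(rg[lin], no, na) & ok
    vals[!inreg] <- NA_integer_
    step_len <- sqrt(1 + sb^2 + sc^2) * voxel_mm
    total_len <- sum(inreg) * step_len
    d <- vals[, -1, drop = FALSE] != vals[, -na, drop = FALSE]
    intercepts <- sum(d, na.rm = TRUE)
    mil[di] <- if (intercepts > 0) total_len / intercepts else total_len
  }
  D <- cbind(directions[, 1]^2, directions[, 2]^2, directions[, 3]^2,
             2 * directions[, 1] * directions[, 2],
             2 * directions[, 1] * directions[, 3],
             2 * directions[, 2] * directions[, 3])
  h <- qr.solve(D, 1 / mil^2)
  H <- matrix(c(h[1], h[4], h[5], h[4], h[2], h[6], h[5], h[6], h[3]), 3, 3)
  ee <- eigen(H, symmetric = TRUE)
  ev <- ee$values
  if (max(ev) <= 0)
    stop("degenerate fabric fit: non-positive-definite MIL ellipsoid")
  # extreme structures (e.g. uninterrupted struts along one axis) can
  # drive a fitted eigenvalue to <= 0: that axis' MIL is effectively
  # unbounded, so clamp to a tiny curvature (DA -> 1)
  ev <- pmax(ev, 1e-12 * max(ev))
  semi <- 1 / sqrt(ev)
  ord <- order(semi, decreasing = TRUE)
  semi <- semi[ord]
  vecs <- ee$vectors[, ord, drop = FALSE]
  structure(list(eigenvalues = semi, eigenvectors = vecs,
                 DA = 1 - semi[3] / semi[1], mil = mil,
                 directions = directions),
            class = "fabric_result")
}

#' @export
print.fabric_result <- function(x, ...) {
  cat(sprintf("<fabric_result> DA = %.3f, semi-axes %.3f / %.3f / %.3f mm\n",
              x$DA, x$eigenvalues[1], x$eigenvalues[2], x$eigenvalues[3]))
  invisible(x)
}
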