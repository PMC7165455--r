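#' Build the femoral-head landmark template
#'
#' The template lives on the unit upper hemisphere (the articular
#' surface analogue), with the head-neck boundary at the equator.  It
#' consists of: 4 fixed corner landmarks at equator azimuths 0/90/180/270
#' degrees (anterior/medial/posterior/lateral), 1 fixed apex landmark at
#' the pole, `n_curve` curve semilandmarks per equator arc strictly
#' between adjacent corners (4 arcs), and `n_surf` surface
#' semilandmarks of which `n_divider` lie on the four meridian arcs
#' between each corner and the apex (dividing the head into quarters);
#' the remainder cover the quarter interiors quasi-evenly (area-uniform
#' spiral seeding followed by Lloyd relaxation on the sphere, fixed
#' iteration count, fully deterministic).
#'
#' @param n_curve curve semilandmarks per arc (default 7).
#' @param n_surf surface semilandmarks (default 208).
#' @param n_divider how many of the surface semilandmarks lie on the
#'   quarter-dividing meridians (default 32; divisible by 4).
#' @return a `landmark_template`: list with `points` (m x 3 on the unit
#'   hemisphere), `role` (`"fixed_corner"`, `"fixed_apex"`, `"curve"`,
#'   `"surface"`), `quarter` (1-4; for curve/divider points the arc or
#'   meridian index), `divider` (logical), plus the counts.
#' @export
build_template <- function(n_curve = 7L, n_surf = 208L, n_divider = 32L) {
  if (n_divider %% 4L != 0L) stop("`n_divider` must be divisible by 4")
  if (n_surf < n_divider) stop("`n_surf` must be >= `n_divider`")
  az <- function(alpha) cbind(sin(alpha), cos(alpha), 0)  # azimuth from +y
  corners <- az(c(0, 0.5, 1, 1.5) * pi)  # anterior, medial, posterior, lateral
  apex <- c(0, 0, 1)
  pts <- rbind(corners, apex)
  role <- c(rep("fixed_corner", 4), "fixed_apex")
  quarter <- c(1:4, NA)
  divider <- rep(FALSE, 5)
  for (q in 1:4) {  # equator arcs between adjacent corners
    a0 <- (q - 1) * pi / 2
    if (n_curve > 0) {
      alpha <- a0 + (seq_len(n_curve) / (n_curve + 1)) * pi / 2
      pts <- rbind(pts, az(alpha))
      role <- c(role, rep("curve", n_curve))
      quarter <- c(quarter, rep(q, n_curve))
      divider <- c(divider, rep(FALSE, n_curve))
    }
  }
  nd4 <- n_divider %/% 4L
  for (q in 1:4) {  # meridians from corner q to apex
    if (nd4 > 0) {
      phi <- (seq_len(nd4) / (nd4 + 1)) * pi / 2  # polar angle from pole
      aq <- (q - 1) * pi / 2
      pts <- rbind(pts, cbind(sin(phi) * sin(aq), sin(phi) * cos(aq),
                              cos(phi)))
      role <- c(role, rep("surface", nd4))
      quarter <- c(quarter, rep(q, nd4))
      divider <- c(divider, rep(TRUE, nd4))
    }
  }
  n_int <- n_surf - n_divider
  per_q <- rep(n_int %/% 4L, 4)
  if (n_int %% 4L) per_q[seq_len(n_int %% 4L)] <- per_q[seq_len(n_int %% 4L)] + 1L
  for (q in 1:4) {
    if (per_q[q] > 0) {
      pq <- quarter_interior_points(q, per_q[q])
      pts <- rbind(pts, pq)
      role <- c(role, rep("surface", per_q[q]))
      quarter <- c(quarter, rep(q, per_q[q]))
      divider <- c(divider, rep(FALSE, per_q[q]))
    }
  }
  structure(list(points = unname(pts), role = role, quarter = quarter,
                 divider = divider, n_curve = n_curve, n_surf = n_surf,
                 n_divider = n_divider),
            class = "landmark_template")
}

#' @export
print.landmark_template <- function(x, ...) {
  cat(sprintf(paste0("<landmark_template> %d points: 5 fixed, %d curve ",
                     "(4 x %d), %d surface (%d on dividers)\n"),
              nrow(x$points), 4 * x$n_curve, x$n_curve, x$n_surf,
              x$n_divider))
  invisible(x)
}

# quasi-even points strictly inside hemisphere quarter q: Fibonacci
# seeding + Lloyd relaxation against a dense candidate cloud (deterministic)
quarter_interior_points <- function(q, k, lloyd_iters = 15L) {
  a0 <- (q - 1) * pi / 2; a1 <- q * pi / 2
  margin <- 0.04
  fib <- function(m) {
    i <- seq_len(m) - 0.5
    z <- 1 - i / m          # hemisphere: z in (0,1)
    phi <- i * pi * (3 - sqrt(5))
    r <- sqrt(pmax(0, 1 - z^2))
    cbind(r * sin(phi), r * cos(phi), z)
  }
  inq <- function(p) {
    alpha <- atan2(p[, 1], p[, 2]) %% (2 * pi)
    pol <- acos(pmin(1, pmax(-1, p[, 3])))
    alpha > a0 + margin & alpha < a1 - margin &
      pol > margin & pol < pi / 2 - margin
  }
  dense <- fib(6000L); dense <- dense[inq(dense), , drop = FALSE]
  seeds <- fib(1200L); seeds <- seeds[inq(seeds), , drop = FALSE]
  if (nrow(seeds) < k) stop("quarter too small for requested point count")
  sel <- seeds[round(seq(1, nrow(seeds), length.out = k)), , drop = FALSE]
  for (it in seq_len(lloyd_iters)) {
    d2 <- outer(rowSums(dense^2), rowSums(sel^2), "+") -
      2 * dense %*% t(sel)
    nn <- max.col(-d2, ties.method = "first")
    for (j in seq_len(k)) {
      c0 <- colMeans(dense[nn == j, , drop = FALSE])
      if (any(!is.finite(c0))) next
      c0 <- c0 / sqrt(sum(c0^2))
      # keep strictly inside the quarter
      if (inq(rbind(c0))) sel[j, ] <- c0
    }
  }
  sel
}

#' Detect the five fixed landmarks on a specimen surface
#'
#' The head-neck boundary is taken as the band of surface vertices near
#' the plane `z = rim_z`; the four corner landmarks are the band's
#' extrema along +y (anterior), +x (medial), -y (posterior) and -x
#' (lateral), and the apex is the surface point above the rim that is
#' most equidistant from the four corners (for a hemisphere, the pole).
#'
#' @param surface a `surface_mesh` of the epiphysis envelope.
#' @param rim_z height (mm) of the head-neck boundary plane (default 0,
#'   the convention of the synthetic generator).
#' @param band_mm half-thickness of the rim band; default 2% of the
#'   head's maximal radial extent.
#' @return 5 x 3 matrix (anterior, medial, posterior, lateral, apex) with
#'   a fitted `surface_circle` rim handle as attribute `"rim"`.
#' @export
detect_fixed_landmarks <- function(surface, rim_z = 0, band_mm = NULL) {
  v <- surface$vertices
  rmax <- max(sqrt(rowSums(sweep(v, 2, c(0, 0, rim_z))^2)))
  if (is.null(band_mm)) band_mm <- 0.02 * rmax
  band <- abs(v[, 3] - rim_z) <= band_mm
  if (sum(band) < 8) stop("head-neck boundary not extractable at rim_z")
  bv <- v[band, , drop = FALSE]
  qs <- atan2(bv[, 1], bv[, 2]) %% (2 * pi)
  if (length(unique(floor(qs / (pi / 2)))) < 4)
    stop("head-neck boundary band does not close around the head")
  anterior <- bv[which.max(bv[, 2]), ]
  medial <- bv[which.max(bv[, 1]), ]
  posterior <- bv[which.min(bv[, 2]), ]
  lateral <- bv[which.min(bv[, 1]), ]
  center <- c(mean(bv[, 1]), mean(bv[, 2]), rim_z)
  radius <- mean(sqrt((bv[, 1] - center[1])^2 + (bv[, 2] - center[2])^2))
  corners <- rbind(anterior, medial, posterior, lateral)
  above <- which(v[, 3] > rim_z + band_mm)
  dc <- sapply(1:4, function(i)
    sqrt(rowSums(sweep(v[above, , drop = FALSE], 2, corners[i, ])^2)))
  spread <- apply(dc, 1, sd)
  apex <- v[above[which.min(spread)], ]
  out <- rbind(anterior, medial, posterior, lateral, apex)
  rownames(out) <- c("anterior", "medial", "posterior", "lateral", "apex")
  attr(out, "rim") <- surface_circle(center, radius, c(0, 0, 1))
  out
}

#' Project the landmark template onto a specimen surface
#'
#' A thin-plate-spline warp is computed from the template's five fixed
#' landmarks to the specimen's, applied to all template points, and the
#' warped semilandmarks are projected onto the specimen surface (curve
#' semilandmarks onto the head-neck rim when a rim handle is supplied).
#' Fixed landmarks map to the specimen's fixed landmarks exactly.
#'
#' @param template a `landmark_template`.
#' @param surface a surface handle (`surface_mesh` or `surface_sphere`).
#' @param fixed_landmarks 5 x 3 matrix in template fixed-point order
#'   (anterior, medial, posterior, lateral, apex).
#' @param rim optional `surface_circle` for the head-neck boundary.
#' @param id specimen identifier.
#' @return a `landmark_set`: template fields plus `points` in specimen
#'   space, `id`, and the `surface` / `rim` handles.
#' @export
project_template <- function(template, surface, fixed_landmarks, rim = NULL,
                             id = "specimen") {
  stopifnot(inherits(template, "landmark_template"))
  fixed_landmarks <- unname(as.matrix(fixed_landmarks))
  stopifnot(nrow(fixed_landmarks) == 5)
  if (qr(cbind(1, fixed_landmarks))$rank < 4)
    stop("degenerate fixed-landmark configuration (collinear/coplanar collapse)")
  src <- template$points[1:5, , drop = FALSE]
  fit <- tps_fit(src, fixed_landmarks)
  warped <- tps_warp(fit, template$points)
  role <- template$role
  pts <- warped
  is_curve <- role == "curve"
  is_surf <- role == "surface"
  if (any(is_surf))
    pts[is_surf, ] <- project_to_surface(surface,
                                         warped[is_surf, , drop = FALSE])$points
  if (any(is_curve)) {
    h <- if (!is.null(rim)) rim else surface
    pts[is_curve, ] <- project_to_surface(h,
                                          warped[is_curve, , drop = FALSE])$points
  }
  pts[1:5, ] <- fixed_landmarks
  structure(list(id = id, points = unname(pts), role = role,
                 quarter = template$quarter, divider = template$divider,
                 surface = surface, rim = rim),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> '%s': %d points (%d fixed, %d curve, %d surface)\n",
              x$id, nrow(x$points), sum(startsWith(x$role, "fixed")),
              sum(x$role == "curve"), sum(x$role == "surface")))
  invisible(x)
}

#' Place the full landmark template on a specimen surface
#'
#' Convenience wrapper: detect fixed landmarks, project the template,
#' then relax semilandmarks by bending energy against the template.
#'
#' @param surface a `surface_mesh`.
#' @param template a `landmark_template`.
#' @param rim_z rim plane height (mm).
#' @param relax run the bending-energy relaxation (default TRUE).
#' @param id specimen identifier.
#' @param ... passed to [relax_bending_energy()].
#' @return a `landmark_set`.
#' @export
place_landmarks <- function(surface, template, rim_z = 0, relax = TRUE,
                            id = "specimen", ...) {
  fixed <- detect_fixed_landmarks(surface, rim_z = rim_z)
  set <- project_template(template, surface, fixed,
                          rim = attr(fixed, "rim"), id = id)
  if (relax) set <- relax_bending_energy(set, template, ...)
  set
}
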