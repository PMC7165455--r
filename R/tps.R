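#' Thin-plate-spline fit between landmark configurations
#'
#' 3D TPS with kernel U(r) = -r (the conditionally positive-definite
#' sign convention, so bending energy is non-negative and vanishes
#' exactly for affine maps).
#'
#' @param x n x 3 source landmarks.
#' @param y n x 3 target landmarks.
#' @return a `tps_fit`: weights `W` (n x 3), affine part `A` (4 x 3),
#'   source points.
#' @export
tps_fit <- function(x, y) {
  x <- unname(as.matrix(x)); y <- unname(as.matrix(y))
  n <- nrow(x)
  stopifnot(nrow(y) == n, n >= 4)
  P <- cbind(1, x)
  if (qr(P)$rank < 4)
    stop("degenerate landmark configuration (coplanar/collinear collapse)")
  K <- -as.matrix(dist(x))
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(y, matrix(0, 4, 3))
  sol <- solve(L, rhs)
  structure(list(W = sol[1:n, , drop = FALSE],
                 A = sol[(n + 1):(n + 4), , drop = FALSE], x = x),
            class = "tps_fit")
}

#' Apply a thin-plate-spline warp to points
#'
#' @param fit a `tps_fit`.
#' @param q m x 3 points to warp.
#' @return m x 3 warped points.
#' @export
tps_warp <- function(fit, q) {
  q <- rbind(q)
  U <- -cross_dist(q, fit$x)
  U %*% fit$W + cbind(1, q) %*% fit$A
}

cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

#' Bending energy matrix of a reference configuration
#'
#' The n x n matrix `Be` such that the TPS bending energy of mapping the
#' reference onto a target `Y` is `sum_d Y[,d]' Be Y[,d]`; zero exactly
#' when `Y` is an affine transform of the reference.
#'
#' @param x n x 3 reference landmarks.
#' @return symmetric positive semidefinite n x n matrix.
#' @export
bending_energy_matrix <- function(x) {
  x <- unname(as.matrix(x))
  n <- nrow(x)
  P <- cbind(1, x)
  K <- -as.matrix(dist(x))
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  Li <- solve(L)
  Be <- Li[1:n, 1:n, drop = FALSE]
  (Be + t(Be)) / 2
}

#' TPS bending energy of a target configuration against a reference
#'
#' @param reference n x 3 reference landmarks (or a precomputed bending
#'   energy matrix).
#' @param target n x 3 target landmarks.
#' @return non-negative scalar.
#' @export
bending_energy <- function(reference, target) {
  Be <- if (is.matrix(reference) && nrow(reference) == ncol(reference) &&
            nrow(reference) == nrow(target))
    reference else bending_energy_matrix(reference)
  target <- unname(as.matrix(target))
  sum(vapply(1:3, function(d)
    drop(target[, d] %*% Be %*% target[, d]), numeric(1)))
}

# orthonormal tangent bases at the current semilandmark positions:
# surface points get 2 tangent directions (plane normal from the surface
# handle), curve points 1 (rim tangent), fixed points none
tangent_directions <- function(set) {
  n <- nrow(set$points)
  tang <- vector("list", n)
  norm_info <- NULL
  is_surf <- set$role == "surface"
  is_curve <- set$role == "curve"
  if (any(is_surf)) {
    pr <- project_to_surface(set$surface, set$points[is_surf, , drop = FALSE])
    nrm <- pr$normals
    ii <- which(is_surf)
    for (k in seq_along(ii)) {
      nv <- nrm[k, ]
      a <- if (abs(nv[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      t1 <- a - nv * sum(a * nv); t1 <- t1 / sqrt(sum(t1^2))
      t2 <- c(nv[2] * t1[3] - nv[3] * t1[2], nv[3] * t1[1] - nv[1] * t1[3],
              nv[1] * t1[2] - nv[2] * t1[1])
      tang[[ii[k]]] <- cbind(t1, t2)
    }
  }
  if (any(is_curve)) {
    h <- if (!is.null(set$rim)) set$rim else set$surface
    pr <- project_to_surface(h, set$points[is_curve, , drop = FALSE])
    ii <- which(is_curve)
    for (k in seq_along(ii)) {
      tv <- if (!is.null(pr$tangents)) pr$tangents[k, ] else {
        nv <- pr$normals[k, ]
        a <- if (abs(nv[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        t1 <- a - nv * sum(a * nv); t1 / sqrt(sum(t1^2))
      }
      tang[[ii[k]]] <- cbind(tv / sqrt(sum(tv^2)))
    }
  }
  tang
}

reproject_set <- function(set) {
  is_surf <- set$role == "surface"
  is_curve <- set$role == "curve"
  if (any(is_surf))
    set$points[is_surf, ] <- project_to_surface(
      set$surface, set$points[is_surf, , drop = FALSE])$points
  if (any(is_curve)) {
    h <- if (!is.null(set$rim)) set$rim else set$surface
    set$points[is_curve, ] <- project_to_surface(
      h, set$points[is_curve, , drop = FALSE])$points
  }
  set
}

#' Relax semilandmarks by minimizing TPS bending energy
#'
#' Iteratively slides semilandmarks within their local tangent spaces
#' (surface points in the tangent plane, curve points along the rim
#' tangent, fixed landmarks immobile) to minimize the TPS bending energy
#' of the specimen configuration against the reference, re-projecting to
#' the surface after every step.  Steps that would increase the energy
#' are retried with half step size and the iteration stops when no
#' decrease is possible or the relative change falls below `tol`.
#'
#' @param set a `landmark_set`.
#' @param reference a `landmark_template`, `landmark_set`, or n x 3
#'   matrix (e.g. a GPA mean shape).
#' @param max_iter maximum sliding iterations.
#' @param tol relative energy-change tolerance.
#' @return the relaxed `landmark_set`; iteration diagnostics in
#'   attribute `"relax_info"` (`converged`, `iterations`, `energy`).
#' @export
relax_bending_energy <- function(set, reference, max_iter = 20L,
                                 tol = 1e-6) {
  ref_pts <- if (inherits(reference, c("landmark_template", "landmark_set")))
    reference$points else unname(as.matrix(reference))
  stopifnot(nrow(ref_pts) == nrow(set$points))
  Be <- bending_energy_matrix(ref_pts)
  e0 <- bending_energy(Be, set$points)
  energy_trace <- e0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    tang <- tangent_directions(set)
    slid <- which(!vapply(tang, is.null, logical(1)))
    if (!length(slid)) { converged <- TRUE; break }
    ncol_t <- vapply(tang[slid], ncol, integer(1))
    p <- sum(ncol_t)
    n <- nrow(set$points)
    Vd <- lapply(1:3, function(d) matrix(0, n, p))
    col0 <- cumsum(c(0, ncol_t))
    for (k in seq_along(slid)) {
      i <- slid[k]; Ti <- tang[[i]]
      for (c in seq_len(ncol(Ti)))
        for (d in 1:3) Vd[[d]][i, col0[k] + c] <- Ti[d, c]
    }
    Y <- set$points
    G <- Be %*% Y
    rhs <- numeric(p); M <- matrix(0, p, p)
    for (d in 1:3) {
      M <- M + t(Vd[[d]]) %*% Be %*% Vd[[d]]
      rhs <- rhs + drop(t(Vd[[d]]) %*% G[, d])
    }
    tpar <- tryCatch(solve(M + diag(1e-10 * max(abs(diag(M))), p), -rhs),
                     error = function(e) rep(0, p))
    step <- 1
    accepted <- FALSE
    for (half in 1:6) {
      Ynew <- Y
      for (d in 1:3)
        Ynew[, d] <- Y[, d] + step * drop(Vd[[d]] %*% tpar)
      trial <- set; trial$points <- Ynew
      trial <- reproject_set(trial)
      e1 <- bending_energy(Be, trial$points)
      if (e1 < e0) { set <- trial; accepted <- TRUE; break }
      step <- step / 2
    }
    if (!accepted) { converged <- TRUE; break }
    energy_trace <- c(energy_trace, e1)
    # change measured against the initial energy scale, so a config that
    # has reached (numerically) zero energy counts as converged
    if (abs(e0 - e1) <= tol * max(energy_trace[1], .Machine$double.eps)) {
      e0 <- e1; converged <- TRUE; break
    }
    e0 <- e1
  }
  if (!converged)
    warning(sprintf(
      "bending-energy relaxation stopped at max_iter = %d (energy %.3e)",
      max_iter, e0))
  attr(set, "relax_info") <- list(converged = converged,
                                  iterations = length(energy_trace) - 1L,
                                  energy = energy_trace)
  set
}
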