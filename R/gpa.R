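#' Generalized Procrustes analysis
#'
#' Iteratively centres, optionally scales to unit centroid size, and
#' rotates (no reflections) each configuration onto the evolving mean
#' shape until the mean changes by less than `tol`.
#'
#' @param shapes list of n x 3 matrices (or `landmark_set`s) with equal
#'   point counts.
#' @param scale remove size (unit centroid size) as well.
#' @param tol convergence tolerance on the mean shape.
#' @param max_iter iteration cap.
#' @return a `procrustes_ensemble`: list with `aligned` (list of n x 3),
#'   `mean` (n x 3, centred, unit centroid size), `centroid_sizes`,
#'   `distances` (per-specimen Procrustes distance to the mean), and the
#'   per-specimen similarity parameters (`rotations`, `scales`,
#'   `translations`) mapping each raw shape to its aligned copy.
#' @export
gpa <- function(shapes, scale = TRUE, tol = 1e-10, max_iter = 100L) {
  pts <- lapply(shapes, function(s)
    if (inherits(s, "landmark_set")) s$points else unname(as.matrix(s)))
  m <- length(pts)
  if (m < 2) stop("need at least 2 configurations")
  n <- nrow(pts[[1]])
  stopifnot(all(vapply(pts, nrow, integer(1)) == n))
  csize <- vapply(pts, function(p)
    sqrt(sum(scale(p, scale = FALSE)^2)), numeric(1))
  if (any(csize == 0)) stop("degenerate zero-size configuration")
  trans <- lapply(pts, colMeans)
  X <- lapply(seq_len(m), function(i) {
    p <- sweep(pts[[i]], 2, trans[[i]])
    if (scale) p / csize[i] else p
  })
  R <- lapply(seq_len(m), function(i) diag(3))
  mshape <- X[[1]]
  for (it in seq_len(max_iter)) {
    for (i in seq_len(m)) {
      s <- svd(t(X[[i]]) %*% mshape)
      d <- sign(det(s$u %*% t(s$v)))
      D <- diag(c(1, 1, d))
      rot <- s$u %*% D %*% t(s$v)
      X[[i]] <- X[[i]] %*% rot
      R[[i]] <- R[[i]] %*% rot
    }
    newmean <- Reduce(`+`, X) / m
    newmean <- sweep(newmean, 2, colMeans(newmean))
    if (scale) newmean <- newmean / sqrt(sum(newmean^2))
    if (sqrt(sum((newmean - mshape)^2)) < tol) { mshape <- newmean; break }
    mshape <- newmean
  }
  dists <- vapply(X, function(x) sqrt(sum((x - mshape)^2)), numeric(1))
  structure(list(aligned = X, mean = mshape, centroid_sizes = csize,
                 distances = dists, rotations = R,
                 scales = if (scale) 1 / csize else rep(1, m),
                 translations = trans),
            class = "procrustes_ensemble")
}

#' @export
print.procrustes_ensemble <- function(x, ...) {
  cat(sprintf("<procrustes_ensemble> %d shapes x %d landmarks; mean distance %.4g\n",
              length(x$aligned), nrow(x$mean), mean(x$distances)))
  invisible(x)
}

#' Ordinary (two-configuration) Procrustes distance
#'
#' Least-squares superimposition of `y` onto `x` (translation, rotation,
#' optional scale, no reflection) and the residual root-sum-of-squares.
#'
#' @param x,y n x 3 matrices.
#' @param scale remove size.
#' @return the Procrustes distance (scalar).
#' @export
procrustes_distance <- function(x, y, scale = TRUE) {
  x <- unname(as.matrix(x)); y <- unname(as.matrix(y))
  xc <- scale(x, scale = FALSE); yc <- scale(y, scale = FALSE)
  if (scale) {
    xc <- xc / sqrt(sum(xc^2)); yc <- yc / sqrt(sum(yc^2))
  }
  s <- svd(t(yc) %*% xc)
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(sum((yc %*% rot - xc)^2))
}

#' Slide cohort semilandmarks toward the Procrustes mean
#'
#' Alternates GPA mean estimation with per-specimen tangential sliding of
#' semilandmarks toward the mean shape (the Procrustes-distance sliding
#' criterion): the mean is mapped back into each specimen's space, the
#' residual at each semilandmark is projected onto its tangent space
#' (plane for surface points, rim tangent for curve points), points move
#' by the projected residual and are re-projected onto their surfaces.
#' Rounds that fail to decrease the total Procrustes sum of squares are
#' rolled back and the procedure stops.
#'
#' @param sets list of `landmark_set`s (mutually corresponding).
#' @param max_rounds maximum slide/GPA rounds.
#' @param scale passed to [gpa()].
#' @return list of slid `landmark_set`s; attribute `"slide_info"` holds
#'   the per-round total Procrustes sum of squares.
#' @export
slide_to_mean <- function(sets, max_rounds = 3L, scale = TRUE) {
  if (max_rounds <= 0L) return(sets)
  ens <- gpa(sets, scale = scale)
  ss <- sum(ens$distances^2)
  trace <- ss
  for (round in seq_len(max_rounds)) {
    trial <- sets
    for (i in seq_along(sets)) {
      set <- sets[[i]]
      # mean shape mapped into specimen space: invert center/scale/rotate
      target <- ens$mean %*% t(ens$rotations[[i]])
      target <- target / ens$scales[i]
      target <- sweep(target, 2, ens$translations[[i]], "+")
      tang <- tangent_directions(set)
      P <- set$points
      for (j in seq_len(nrow(P))) {
        Tj <- tang[[j]]
        if (is.null(Tj)) next
        r <- target[j, ] - P[j, ]
        P[j, ] <- P[j, ] + drop(Tj %*% (t(Tj) %*% r))
      }
      set$points <- P
      trial[[i]] <- reproject_set(set)
    }
    ens2 <- gpa(trial, scale = scale)
    ss2 <- sum(ens2$distances^2)
    if (ss2 >= ss - 1e-14) break
    sets <- trial; ens <- ens2; ss <- ss2
    trace <- c(trace, ss)
  }
  attr(sets, "slide_info") <- list(procrustes_ss = trace)
  sets
}
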