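#' BV/TV at landmark positions from a scalar mesh
#'
#' Each landmark takes the BV/TV of the nearest mesh element (by
#' centroid; exhaustive nearest search, so results are exact).  Errors
#' if any landmark lies farther than `max_dist_mm` from every element.
#'
#' @param set a `landmark_set` (or n x 3 matrix of points).
#' @param mesh a `scalar_mesh`.
#' @param max_dist_mm maximum landmark-to-element distance (default 2).
#' @return numeric vector of per-landmark BV/TV; assignment distances in
#'   attribute `"distance_mm"`.
#' @export
bvtv_at_landmarks <- function(set, mesh, max_dist_mm = 2) {
  p <- if (inherits(set, "landmark_set")) set$points else rbind(set)
  ctr <- mesh$centers
  d2 <- outer(rowSums(p^2), rowSums(ctr^2), "+") - 2 * p %*% t(ctr)
  nn <- max.col(-d2, ties.method = "first")
  dist_mm <- sqrt(pmax(0, d2[cbind(seq_len(nrow(p)), nn)]))
  if (any(dist_mm > max_dist_mm))
    stop(sprintf("%d landmark(s) farther than %g mm from the scalar mesh",
                 sum(dist_mm > max_dist_mm), max_dist_mm))
  out <- mesh$values[nn]
  attr(out, "distance_mm") <- dist_mm
  out
}

#' Relative BV/TV (RBV/TV) standardization of one specimen
#'
#' Divides a specimen's landmark BV/TV values by their mean, so the
#' standardized row has mean exactly 1 and comparisons between specimens
#' reflect the shape of the distribution rather than overall bone volume.
#'
#' @param values numeric vector of landmark BV/TV for one specimen.
#' @return numeric vector of the same length with mean 1.
#' @export
rbvtv <- function(values) {
  m <- mean(values)
  if (!is.finite(m) || m <= 0)
    stop("specimen mean BV/TV must be positive to standardize")
  values / m
}

#' Assemble the specimens x landmarks RBV/TV matrix
#'
#' @param bvtv_rows list (or matrix) of per-specimen landmark BV/TV
#'   vectors, all the same length.
#' @param ids specimen identifiers.
#' @param groups group labels.
#' @return an `rbvtv_matrix`: list with `x` (specimens x landmarks,
#'   every row mean 1), `ids`, `groups`.
#' @export
rbvtv_matrix <- function(bvtv_rows, ids = NULL, groups = NULL) {
  if (is.list(bvtv_rows)) bvtv_rows <- do.call(rbind, bvtv_rows)
  x <- t(apply(bvtv_rows, 1, rbvtv))
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(nrow(x)))
  structure(list(x = unname(x), ids = ids, groups = groups),
            class = "rbvtv_matrix")
}

#' PCA of an RBV/TV matrix
#'
#' Column-mean-centred, unscaled (covariance) PCA via SVD.  Component
#' signs follow a deterministic convention: the largest-magnitude
#' loading of each component is positive.
#'
#' @param mat an `rbvtv_matrix` (or plain specimens x variables matrix).
#' @return a `pca_result`: `scores` (specimens x components), `loadings`
#'   (variables x components), `variance_fraction`, `sdev`, plus the
#'   `ids` / `groups` carried through.
#' @export
pca_rbvtv <- function(mat) {
  x <- if (inherits(mat, "rbvtv_matrix")) mat$x else unname(as.matrix(mat))
  if (nrow(x) < 3) stop("PCA needs at least 3 specimens")
  xc <- scale(x, scale = FALSE)
  sv <- svd(xc)
  k <- sum(sv$d > sv$d[1] * 1e-12)
  k <- max(k, 1L)
  scores <- sv$u[, 1:k, drop = FALSE] %*% diag(sv$d[1:k], k)
  loadings <- sv$v[, 1:k, drop = FALSE]
  for (j in 1:k) {
    s <- sign(loadings[which.max(abs(loadings[, j])), j])
    if (s < 0) { loadings[, j] <- -loadings[, j]; scores[, j] <- -scores[, j] }
  }
  var_total <- sum(xc^2)
  vf <- sv$d[1:k]^2 / var_total
  structure(list(scores = scores, loadings = loadings,
                 variance_fraction = vf,
                 sdev = sv$d[1:k] / sqrt(nrow(x) - 1),
                 ids = if (inherits(mat, "rbvtv_matrix")) mat$ids,
                 groups = if (inherits(mat, "rbvtv_matrix")) mat$groups),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d specimens, PC1-3 variance %s\n",
              nrow(x$scores),
              paste(sprintf("%.1f%%", 100 * head(x$variance_fraction, 3)),
                    collapse = " / ")))
  invisible(x)
}

#' Choose the number of principal components to test
#'
#' @param pca a `pca_result`.
#' @param rule `"first3"` (the default: always 3, capped at the number of
#'   available components) or `"cumulative50"` (smallest k whose
#'   cumulative variance fraction exceeds 0.5).
#' @return integer number of components.
#' @export
choose_components <- function(pca, rule = c("first3", "cumulative50")) {
  rule <- match.arg(rule)
  k <- switch(rule,
              first3 = min(3L, length(pca$variance_fraction)),
              cumulative50 = which(cumsum(pca$variance_fraction) > 0.5)[1])
  as.integer(k)
}

#' Pairwise one-way permutational MANOVA on PC scores
#'
#' For every pair of groups, computes Anderson's pseudo-F from the
#' Euclidean distance matrix of the pair's scores on the first
#' `n_components` PCs, F = (SS_between/(a-1)) / (SS_within/(N-a)), and a
#' permutation p-value under label permutation with the add-one
#' convention p = (1 + #[F* >= F]) / (1 + n_perm).  P-values are
#' Bonferroni-adjusted by the number of pairs performed.  With
#' `method = "exact"`, all distinct label assignments are enumerated
#' instead (small samples).
#'
#' @param scores specimens x components matrix (or a `pca_result`).
#' @param labels group label per specimen (>= 2 per group).
#' @param n_components PCs used (default 3).
#' @param n_perm permutations (default 9999).
#' @param seed integer seed for the permutation draw.
#' @param method `"permutation"` or `"exact"`.
#' @return a `permanova_table` data frame: group pair, pseudo-F,
#'   p-value, Bonferroni-adjusted p-value, group sizes; attributes
#'   `n_perm`, `seed`, `n_components`.
#' @export
pairwise_permanova <- function(scores, labels, n_components = 3L,
                               n_perm = 9999L, seed = 1L,
                               method = c("permutation", "exact")) {
  method <- match.arg(method)
  if (inherits(scores, "pca_result")) {
    if (is.null(labels)) labels <- scores$groups
    scores <- scores$scores
  }
  labels <- as.character(labels)
  stopifnot(nrow(scores) == length(labels))
  if (n_components > ncol(scores))
    stop("n_components exceeds available components")
  tab <- table(labels)
  if (any(tab < 2)) stop("every group needs at least 2 members")
  gs <- names(tab)
  pairs <- combn(gs, 2)
  npairs <- ncol(pairs)
  res <- data.frame(group_a = character(0), group_b = character(0),
                    n_a = integer(0), n_b = integer(0), F = numeric(0),
                    p = numeric(0), p_adjusted = numeric(0),
                    degenerate = logical(0))
  set.seed(seed)
  for (pi in seq_len(npairs)) {
    ga <- pairs[1, pi]; gb <- pairs[2, pi]
    sel <- labels %in% c(ga, gb)
    y <- scores[sel, seq_len(n_components), drop = FALSE]
    lab <- labels[sel]
    d2 <- as.matrix(dist(y))^2
    n <- nrow(y)
    stat <- function(grp_is_a) {
      na <- sum(grp_is_a); nb <- n - na
      ss_tot <- sum(d2) / (2 * n)
      ss_w <- sum(d2[grp_is_a, grp_is_a]) / (2 * na) +
        sum(d2[!grp_is_a, !grp_is_a]) / (2 * nb)
      ss_b <- ss_tot - ss_w
      if (ss_w <= 1e-14 * max(ss_tot, 1e-300)) return(Inf)
      (ss_b / 1) / (ss_w / (n - 2))
    }
    obs_is_a <- lab == ga
    f_obs <- stat(obs_is_a)
    degenerate <- !is.finite(f_obs)
    if (method == "exact") {
      na <- sum(obs_is_a)
      combos <- combn(n, na)
      f_perm <- apply(combos, 2, function(ii) {
        g <- rep(FALSE, n); g[ii] <- TRUE; stat(g)
      })
      # exact p over all distinct assignments (the observed one included)
      p <- mean(f_perm >= f_obs - 1e-12)
    } else {
      f_perm <- vapply(seq_len(n_perm), function(b) {
        stat(sample(obs_is_a)) }, numeric(1))
      p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_perm)
    }
    if (degenerate) p <- NA_real_
    res <- rbind(res, data.frame(
      group_a = ga, group_b = gb, n_a = sum(obs_is_a),
      n_b = sum(!obs_is_a), F = f_obs, p = p, p_adjusted = NA_real_,
      degenerate = degenerate))
  }
  res$p_adjusted <- pmin(1, res$p * npairs)
  structure(res, class = c("permanova_table", "data.frame"),
            n_perm = n_perm, seed = seed, n_components = n_components,
            method = method)
}
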