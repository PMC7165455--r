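test_that("landmark BV/TV uses the nearest element, exactly", {
  mesh <- toy_mesh()
  # exact hit
  v <- bvtv_at_landmarks(rbind(mesh$centers[37, ]), mesh)
  expect_equal(as.numeric(v), mesh$values[37])
  # 50 random landmarks vs exhaustive O(n) search
  set.seed(23)
  p <- matrix(runif(150, 1, 8), 50, 3)
  v <- bvtv_at_landmarks(p, mesh)
  for (i in 1:50) {
    d2 <- colSums((t(mesh$centers) - p[i, ])^2)
    expect_equal(as.numeric(v)[i], mesh$values[which.min(d2)])
  }
  # far landmarks are rejected
  expect_error(bvtv_at_landmarks(rbind(c(50, 50, 50)), mesh), "farther")
})

test_that("RBV/TV standardization has mean one and is scale-free", {
  expect_equal(rbvtv(rep(0.37, 10)), rep(1, 10))
  v <- c(0.2, 0.4)
  expect_equal(rbvtv(v), c(2 / 3, 4 / 3))
  set.seed(3); w <- runif(50, 0.1, 0.6)
  expect_equal(rbvtv(w), rbvtv(3.7 * w), tolerance = 1e-12)
  expect_equal(mean(rbvtv(w)), 1, tolerance = 1e-12)
  expect_error(rbvtv(c(-1, 1)), "positive")
  rb <- rbvtv_matrix(list(runif(20), runif(20), runif(20)),
                     groups = c("a", "a", "b"))
  expect_equal(rowMeans(rb$x), rep(1, 3), tolerance = 1e-12)
})

test_that("covariance PCA satisfies its algebraic identities", {
  set.seed(9)
  base <- matrix(rnorm(2 * 12), 2, 12)
  x <- matrix(rnorm(8 * 2), 8, 2) %*% base  # exact rank 2
  p <- pca_rbvtv(x)
  expect_lt(sum(p$variance_fraction[-(1:2)]), 1e-9)
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-9)
  xc <- scale(x, scale = FALSE)
  expect_lt(max(abs(xc - p$scores %*% t(p$loadings))), 1e-9)
  # deterministic sign convention
  for (j in seq_len(ncol(p$loadings)))
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  expect_error(pca_rbvtv(x[1:2, ]), "at least 3")
})

test_that("component choice rules behave as specified", {
  p <- list(variance_fraction = c(0.6, 0.2, 0.1, 0.1))
  expect_equal(choose_components(p, "first3"), 3L)
  expect_equal(choose_components(p, "cumulative50"), 1L)
  p2 <- list(variance_fraction = c(0.3, 0.15, 0.1, 0.45))
  expect_equal(choose_components(p2, "cumulative50"), 3L)
  p3 <- list(variance_fraction = c(0.5, 0.5))
  expect_equal(choose_components(p3, "first3"), 2L)
})

test_that("permutation p-values match exact enumeration for small samples", {
  set.seed(31)
  sc <- matrix(rnorm(8 * 3), 8, 3)
  sc[1:4, 1] <- sc[1:4, 1] + 1.5
  lab <- rep(c("a", "b"), each = 4)
  ex <- pairwise_permanova(sc, lab, n_components = 3, method = "exact")
  mc <- pairwise_permanova(sc, lab, n_components = 3, n_perm = 9999,
                           seed = 4)
  expect_lt(abs(ex$p - mc$p), 1 / 71)
  expect_equal(nrow(ex), 1L)
})

test_that("pseudo-F agrees with an independent PERMANOVA implementation", {
  set.seed(41)
  sc <- matrix(rnorm(18 * 3), 18, 3)
  lab <- rep(c("a", "b"), each = 9)
  ours <- pairwise_permanova(sc, lab, n_components = 3, n_perm = 99,
                             seed = 1)
  ref <- vegan::adonis2(dist(sc) ~ g, data = data.frame(g = lab),
                        permutations = 99)
  expect_equal(ours$F, ref$F[1], tolerance = 1e-9)
})

test_that("extreme separation gives the minimum p, degeneracy is flagged", {
  set.seed(51)
  sc <- matrix(rnorm(12 * 3, sd = 0.5), 12, 3)
  sc[7:12, ] <- sc[7:12, ] + 50
  lab <- rep(c("a", "b"), each = 6)
  r <- pairwise_permanova(sc, lab, n_perm = 999, seed = 2)
  # permutations reproducing the observed split (or its complement) tie
  # with the observed F, so the attainable minimum sits just above the
  # add-one floor 1/(n_perm+1)
  expect_gte(r$p, 1 / 1000)
  expect_lt(r$p, 0.01)
  expect_equal(r$p_adjusted, r$p)  # single pair
  # identical scores within both groups: degenerate, not p = 0
  sc0 <- matrix(rep(c(0, 10), each = 4 * 3), ncol = 3, byrow = FALSE)
  sc0 <- rbind(matrix(0, 4, 3), matrix(10, 4, 3))
  r0 <- pairwise_permanova(sc0, rep(c("a", "b"), each = 4), n_perm = 99,
                           seed = 1)
  expect_true(r0$degenerate)
  expect_true(is.na(r0$p))
  expect_error(pairwise_permanova(matrix(rnorm(9), 3, 3), c("a", "a", "b")),
               "at least 2")
})

test_that("statistics are exchangeable under specimen reordering", {
  set.seed(61)
  sc <- matrix(rnorm(14 * 3), 14, 3)
  lab <- rep(c("a", "b"), 7)
  perm <- sample(14)
  r1 <- pairwise_permanova(sc, lab, n_perm = 499, seed = 3)
  r2 <- pairwise_permanova(sc[perm, ], lab[perm], n_perm = 499, seed = 3)
  expect_equal(r1$F, r2$F, tolerance = 1e-12)
  # reseeding moves p by at most Monte-Carlo error
  r3 <- pairwise_permanova(sc, lab, n_perm = 499, seed = 99)
  mc_se <- sqrt(r1$p * (1 - r1$p) / 499)
  expect_lt(abs(r1$p - r3$p), 5 * mc_se + 2 / 500)
})

test_that("Bonferroni adjustment multiplies by the number of pairs", {
  set.seed(71)
  sc <- matrix(rnorm(18 * 3), 18, 3)
  lab <- rep(c("a", "b", "c"), each = 6)
  r <- pairwise_permanova(sc, lab, n_perm = 199, seed = 5)
  expect_equal(nrow(r), 3L)
  expect_equal(r$p_adjusted, pmin(1, r$p * 3))
})
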