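test_that("TPS interpolates its anchors and warps smoothly", {
  set.seed(5)
  x <- rand_shape(12, 5)
  y <- x + matrix(rnorm(36, sd = 0.1), 12, 3)
  fit <- tps_fit(x, y)
  expect_lt(max(abs(tps_warp(fit, x) - y)), 1e-8)
  expect_error(tps_fit(cbind(1:5, 0, 0), matrix(rnorm(15), 5, 3)),
               "degenerate")
})

test_that("bending energy vanishes exactly for affine maps and is positive otherwise", {
  x <- rand_shape(15, 2)
  A <- matrix(rnorm(9), 3, 3)
  y_aff <- x %*% A + rep(1, 15) %o% c(3, -1, 2)
  expect_lt(bending_energy(x, y_aff), 1e-10)
  y_bent <- y_aff; y_bent[1, ] <- y_bent[1, ] + 1
  expect_gt(bending_energy(x, y_bent), 1e-6)
  # the bending-energy matrix is PSD
  Be <- bending_energy_matrix(x)
  ev <- eigen(Be, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10)
})

test_that("relaxation is a no-op at the reference and reduces energy otherwise", {
  tpl <- fixture("template", build_template)
  sph <- surface_sphere(c(0, 0, 0), 1)
  rim <- surface_circle(c(0, 0, 0), 1, c(0, 0, 1))
  set <- structure(list(id = "t", points = tpl$points, role = tpl$role,
                        quarter = tpl$quarter, divider = tpl$divider,
                        surface = sph, rim = rim), class = "landmark_set")
  out <- relax_bending_energy(set, tpl, max_iter = 5)
  info <- attr(out, "relax_info")
  expect_lt(max(abs(out$points - tpl$points)), 1e-9)
  expect_lt(tail(info$energy, 1), 1e-9)
})

test_that("relaxation strictly reduces energy for tangential perturbations", {
  tpl <- fixture("template", build_template)
  sph <- surface_sphere(c(0, 0, 0), 1)
  rim <- surface_circle(c(0, 0, 0), 1, c(0, 0, 1))
  Be <- bending_energy_matrix(tpl$points)
  for (s in 1:20) {
    set.seed(s)
    p <- tpl$points
    sl <- tpl$role %in% c("curve", "surface")
    noise <- matrix(rnorm(sum(sl) * 3, sd = 0.02), ncol = 3)
    # tangential component only, then back to the sphere
    nrm <- p[sl, ] / sqrt(rowSums(p[sl, ]^2))
    noise <- noise - nrm * rowSums(noise * nrm)
    p[sl, ] <- p[sl, ] + noise
    p[sl, ] <- p[sl, ] / sqrt(rowSums(p[sl, ]^2))
    set <- structure(list(id = "t", points = p, role = tpl$role,
                          quarter = tpl$quarter, divider = tpl$divider,
                          surface = sph, rim = rim), class = "landmark_set")
    e0 <- bending_energy(Be, p)
    out <- relax_bending_energy(set, tpl, max_iter = 3)
    e1 <- tail(attr(out, "relax_info")$energy, 1)
    expect_lt(e1, e0)
    # the energy trace is non-increasing
    expect_true(all(diff(attr(out, "relax_info")$energy) <= 0))
  }
})

test_that("GPA recovers similarity-equivalent shapes", {
  x <- rand_shape(20, 7)
  expect_equal(procrustes_distance(x, x), 0, tolerance = 1e-12)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  y <- 2.5 * x %*% R + rep(1, 20) %o% c(5, -3, 1)
  expect_lt(procrustes_distance(x, y), 1e-9)
  ens <- gpa(list(x, y))
  expect_lt(sum(ens$distances), 1e-9)
  expect_equal(sum(ens$mean^2), 1, tolerance = 1e-9)
  expect_equal(colMeans(ens$mean), c(0, 0, 0), tolerance = 1e-9)
})

test_that("GPA refuses reflections and degenerate input", {
  x <- rand_shape(10, 3)
  y <- x %*% diag(c(-1, 1, 1))  # reflected copy
  expect_gt(procrustes_distance(x, y), 0.05)
  expect_error(gpa(list(x)), "at least 2")
  expect_error(gpa(list(x * 0, x * 0)), "zero-size")
})

test_that("GPA agrees with an independent Procrustes implementation", {
  set.seed(13)
  shapes <- lapply(1:3, function(i) {
    tpl <- fixture("template", build_template)
    tpl$points + matrix(rnorm(nrow(tpl$points) * 3, sd = 0.02), ncol = 3)
  })
  # two-shape cross-check against vegan's symmetric Procrustes: vegan
  # additionally rescales one shape by the optimal factor s = sum of the
  # singular values (ss = 1 - s^2), whereas the chordal distance keeps
  # both at unit size (d^2 = 2 - 2 s); the two are exactly related
  v <- vegan::procrustes(shapes[[1]], shapes[[2]], symmetric = TRUE)
  s <- sqrt(1 - v$ss)
  expect_equal(procrustes_distance(shapes[[1]], shapes[[2]]),
               sqrt(2 - 2 * s), tolerance = 1e-6)
  # ensemble mean distances are consistent with pairwise distances
  ens <- gpa(shapes)
  for (i in 1:3)
    expect_lt(abs(sqrt(sum((ens$aligned[[i]] - ens$mean)^2)) -
                  ens$distances[i]), 1e-12)
})

test_that("sliding to the mean removes spacing artifacts", {
  tpl <- fixture("template", build_template)
  sph <- surface_sphere(c(0, 0, 0), 1)
  rim <- surface_circle(c(0, 0, 0), 1, c(0, 0, 1))
  mkset <- function(p, id) structure(
    list(id = id, points = p, role = tpl$role, quarter = tpl$quarter,
         divider = tpl$divider, surface = sph, rim = rim),
    class = "landmark_set")
  # same geometry; second specimen has its equator curve points respaced
  p2 <- tpl$points
  cur <- which(tpl$role == "curve")
  az <- atan2(p2[cur, 1], p2[cur, 2]) %% (2 * pi)
  corner_az <- (tpl$quarter[cur] - 1) * pi / 2
  frac <- (az - corner_az) / (pi / 2)
  az2 <- corner_az + (frac^1.5) * pi / 2    # skewed spacing along each arc
  p2[cur, ] <- cbind(sin(az2), cos(az2), 0)
  sets <- list(mkset(tpl$points, "a"), mkset(p2, "b"))
  d_pre <- procrustes_distance(sets[[1]]$points, sets[[2]]$points)
  slid <- slide_to_mean(sets, max_rounds = 4)
  d_post <- procrustes_distance(slid[[1]]$points, slid[[2]]$points)
  expect_lt(d_post, 0.5 * d_pre)
  # identical sets do not move; zero rounds is a no-op
  same <- list(mkset(tpl$points, "a"), mkset(tpl$points, "b"))
  slid0 <- slide_to_mean(same, max_rounds = 2)
  expect_lt(max(abs(slid0[[1]]$points - tpl$points)), 1e-9)
  none <- slide_to_mean(sets, max_rounds = 0)
  expect_identical(none[[1]]$points, sets[[1]]$points)
})
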