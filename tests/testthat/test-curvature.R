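test_that("curvature is zero on a plane and 1/3 for an isotropic neighborhood", {
  set.seed(10)
  flat <- point_cloud(cbind(runif(200, 0, 10), runif(200, 0, 10), 0))
  cv <- compute_curvature(flat, curvature_config(3))
  expect_lt(max(cv$features), 1e-12)

  # octahedral neighborhood about the query: equal eigenvalues
  d <- 2
  octa <- point_cloud(rbind(c(0, 0, 0),
                            c(d, 0, 0), c(-d, 0, 0),
                            c(0, d, 0), c(0, -d, 0),
                            c(0, 0, d), c(0, 0, -d)))
  cv <- compute_curvature(octa, curvature_config(3, min_neighbors = 3))
  expect_equal(cv$features[1], 1 / 3, tolerance = 1e-12)
})

test_that("curvature matches an explicit covariance / characteristic-polynomial oracle", {
  # fixed 8-point neighborhood; the whole cloud lies within the radius
  pts <- rbind(c(0.0, 0.0, 0.0), c(1.2, 0.3, 0.1), c(-0.8, 1.1, -0.2),
               c(0.5, -1.0, 0.4), c(-1.1, -0.7, 0.2), c(0.9, 0.8, -0.3),
               c(-0.2, 0.1, 0.8), c(0.3, -0.4, -0.6))
  cl <- point_cloud(pts)
  cv <- compute_curvature(cl, curvature_config(10, min_neighbors = 3))

  # oracle: covariance about the centroid, eigenvalues via polyroot on
  # the characteristic polynomial det(C - lambda I)
  C <- crossprod(sweep(pts, 2, colMeans(pts)))
  cpoly <- c(-det(C),
             C[1, 1] * C[2, 2] + C[1, 1] * C[3, 3] + C[2, 2] * C[3, 3] -
               C[1, 2]^2 - C[1, 3]^2 - C[2, 3]^2,
             -(C[1, 1] + C[2, 2] + C[3, 3]),
             1)
  lam <- sort(Re(polyroot(cpoly)), decreasing = TRUE)
  expect_equal(cv$features[1], lam[3] / sum(lam), tolerance = 1e-9)
})

test_that("curvature is invariant under rigid motion and uniform scaling", {
  cl <- make_phantom(21, 900)
  cfg <- curvature_config(5)
  base <- compute_curvature(cl, cfg)

  set.seed(22)
  moved <- compute_curvature(apply_transform(cl, random_rigid()), cfg)
  expect_lt(max(abs(moved$features - base$features)), 1e-9)

  for (s in c(0.5, 2.0)) {
    scaled <- compute_curvature(point_cloud(cl$points * s),
                                curvature_config(5 * s))
    expect_lt(max(abs(scaled$features - base$features)), 1e-9)
  }
  expect_true(all(base$features >= 0 & base$features <= 1 / 3))
})

test_that("degenerate neighborhoods get sigma 0 and are counted", {
  # two tight clusters far apart plus one isolated point
  set.seed(23)
  a <- matrix(rnorm(30, sd = 0.5), 10, 3)
  iso <- c(100, 100, 100)
  cl <- point_cloud(rbind(a, iso))
  cv <- compute_curvature(cl, curvature_config(2, min_neighbors = 5))
  expect_equal(cv$features[11], 0)
  expect_gte(attr(cv, "n_degenerate"), 1L)
})
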