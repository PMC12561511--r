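test_that("phantom generation is deterministic with the requested size and curvature spread", {
  a <- make_phantom(90, 900)
  b <- make_phantom(90, 900)
  expect_identical(a$points, b$points)
  expect_equal(n_points(a), 900L)
  expect_error(make_phantom(1, 100), ">= 500")

  cv <- compute_curvature(make_phantom(91, 2000), curvature_config(5))
  expect_gte(max(cv$features) - min(cv$features), 0.05)
})

test_that("synthetic pairs are bit-reproducible and internally consistent", {
  spec <- pair_spec(n_preop = 2000, density_ratio = 2, seed = 92)
  p1 <- make_pair(spec)
  p2 <- make_pair(spec)
  expect_identical(p1$preop$points, p2$preop$points)
  expect_identical(p1$intraop$points, p2$intraop$points)
  expect_identical(transform_matrix(p1$ground_truth),
                   transform_matrix(p2$ground_truth))
  expect_identical(p1$achieved_overlap, p2$achieved_overlap)

  # ground truth scores zero error against itself by construction
  # acos amplifies rounding near its endpoint, hence the loose bound
  e <- registration_error(p1$ground_truth, p1$ground_truth)
  expect_lt(e$rotation_error_deg, 1e-4)
  expect_lt(e$translation_error_mm, 1e-9)

  # achieved overlap is near its target over several seeds
  for (s in 1:8) {
    sp <- pair_spec(n_preop = 2000, overlap_target = 0.03,
                    density_ratio = 2, seed = 930 + s)
    p <- make_pair(sp)
    expect_gte(p$achieved_overlap, 0.7 * 0.03)
    expect_lte(p$achieved_overlap, 1.3 * 0.03)
  }
})

test_that("noise-free unit-density pairs are exact subsets under the ground truth", {
  sp <- pair_spec(n_preop = 2000, density_ratio = 1, seed = 95,
                  rotation_range_deg = 1e-12, translation_range_mm = 1e-12)
  p <- make_pair(sp)
  nn <- spinereg:::knn_cpp(p$intraop$points, p$preop$points, 1L, FALSE)
  expect_lt(max(nn$dist[, 1]), 1e-9)
})

test_that("overlap_ratio equals a brute-force tau-ball count", {
  cl <- make_phantom(96, 1000)
  expect_equal(overlap_ratio(cl, cl, identity_transform()), 1.0)

  half <- subset_cloud(cl, 1:500)
  tau <- 1e-9
  got <- overlap_ratio(cl, half, identity_transform(), tau = tau)
  expect_equal(got, 0.5)

  set.seed(97)
  TG <- random_rigid()
  crop <- subset_cloud(cl, sample(1000, 200))
  moved <- apply_transform(crop, invert(TG))
  tau <- 2 * median_nn_spacing(cl)
  got <- overlap_ratio(cl, moved, TG, tau = tau)
  back <- apply_transform(moved, TG)$points
  d2 <- outer(rowSums(cl$points^2), rep(1, 200)) -
    2 * cl$points %*% t(back) +
    outer(rep(1, 1000), rowSums(back^2))
  dmin <- sqrt(pmax(apply(d2, 1, min), 0))
  expect_equal(got, mean(dmin <= tau + 1e-12))
})

test_that("pose draws span the configured rotation and translation ranges", {
  rots <- matrix(NA_real_, 200, 3)
  trans <- matrix(NA_real_, 200, 3)
  for (s in 1:200) {
    p <- make_pair(pair_spec(n_preop = 600, density_ratio = 1.2,
                             seed = 5000 + s))
    rots[s, ] <- abs(p$pose_angles_deg)
    trans[s, ] <- abs(p$pose_translation_mm)
    # the stored metadata must describe the applied pose
    A <- invert(p$ground_truth)
    R <- rot_z(p$pose_angles_deg[3]) %*% rot_y(p$pose_angles_deg[2]) %*%
      rot_x(p$pose_angles_deg[1])
    expect_lt(max(abs(A$rotation - R)), 1e-9)
  }
  for (ax in 1:3) {
    expect_lte(min(rots[, ax]), 10)
    expect_gte(max(rots[, ax]), 150)
    expect_lte(min(trans[, ax]), 10)
    expect_gte(max(trans[, ax]), 100)
  }
})

test_that("the additive noise model has the requested per-coordinate variance", {
  base <- make_pair(pair_spec(n_preop = 2000, n_intraop = 4000, seed = 98))
  for (sg in c(0.25, 0.5, 1.0)) {
    noisy <- renoise_pair(base, sg)
    expect_identical(noisy$preop$points, base$preop$points)
    diffs <- as.vector(noisy$intraop$points - base$intraop$points)
    expect_gte(length(diffs), 1e4)
    expect_lt(abs(var(diffs) - sg^2) / sg^2, 0.1)
  }
  # re-noising at sigma 0 reproduces the clean geometry
  clean <- renoise_pair(base, 0)
  expect_equal(clean$intraop$points, base$intraop$points, tolerance = 1e-12)
})
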