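test_that("rigid transform algebra satisfies the group laws", {
  expect_equal(transform_matrix(invert(identity_transform())), diag(4))

  # two z-rotations compose to their angle sum
  T30 <- compose(rigid_transform(rot_z(10)), rigid_transform(rot_z(20)))
  expect_equal(T30$rotation, rot_z(30), tolerance = 1e-12)

  set.seed(42)
  for (i in 1:100) {
    T1 <- random_rigid()
    rt <- compose(T1, invert(T1))
    expect_lt(max(abs(rt$rotation - diag(3))), 1e-9)
    expect_lt(max(abs(rt$translation)), 1e-9)
  }
  # associativity on sampled triples
  set.seed(7)
  for (i in 1:20) {
    Ts <- list(random_rigid(), random_rigid(), random_rigid())
    A <- compose(compose(Ts[[1]], Ts[[2]]), Ts[[3]])
    B <- compose(Ts[[1]], compose(Ts[[2]], Ts[[3]]))
    expect_lt(max(abs(transform_matrix(A) - transform_matrix(B))), 1e-9)
  }
})

test_that("invalid rotations are rejected rather than repaired", {
  M <- diag(3); M[1, 1] <- 1 + 1e-3
  expect_error(rigid_transform(M), "orthonormal")
  R <- diag(3); R[3, 3] <- -1  # reflection
  expect_error(rigid_transform(R), "determinant")
})

test_that("apply_transform acts as R p + t and preserves rigidity", {
  cl <- point_cloud(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  moved <- apply_transform(cl, rigid_transform(diag(3), c(3, 4, 0)))
  expect_equal(moved$points[1, ], c(3, 4, 0))

  expect_equal(apply_transform(cl, identity_transform())$points, cl$points)

  set.seed(1)
  cl <- scatter_cloud(60, seed = 2)
  T1 <- random_rigid()
  back <- apply_transform(apply_transform(cl, T1), invert(T1))
  expect_lt(max(abs(back$points - cl$points)), 1e-9)

  d0 <- as.matrix(dist(cl$points))
  d1 <- as.matrix(dist(apply_transform(cl, T1)$points))
  expect_lt(max(abs(d0 - d1)), 1e-6)
})

test_that("registration_error matches the closed-form rotation/translation errors", {
  TG <- identity_transform()
  e <- registration_error(TG, TG)
  expect_equal(e$rotation_error_deg, 0)
  expect_equal(e$translation_error_mm, 0)

  e30 <- registration_error(rigid_transform(rot_z(30)), TG)
  expect_equal(e30$rotation_error_deg, 30, tolerance = 1e-9)

  et <- registration_error(rigid_transform(diag(3), c(3, 4, 0)), TG)
  expect_equal(et$translation_error_mm, 5)

  # left-invariance under a shared rigid motion: the rotation error is
  # invariant for any rigid S; the translation error only when S is a
  # pure rotation (the residual transform is conjugated by S, which
  # mixes S's translation into the residual translation otherwise)
  set.seed(3)
  for (i in 1:20) {
    S <- random_rigid(); T1 <- random_rigid(); TG <- random_rigid()
    a <- registration_error(T1, TG)
    b <- registration_error(compose(S, T1), compose(S, TG))
    expect_lt(abs(a$rotation_error_deg - b$rotation_error_deg), 1e-9)
    S_rot <- rigid_transform(S$rotation, c(0, 0, 0))
    c2 <- registration_error(compose(S_rot, T1), compose(S_rot, TG))
    expect_lt(abs(a$rotation_error_deg - c2$rotation_error_deg), 1e-9)
    expect_lt(abs(a$translation_error_mm - c2$translation_error_mm), 1e-9)
  }
})

test_that("XYZ files round-trip including comments and the feature column", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("# comment line", "0 0 0", "1 0 0", "0 1 0"), f)
  cl <- read_point_cloud(f)
  expect_equal(n_points(cl), 3L)
  expect_null(cl$features)

  cl2 <- point_cloud(scatter_cloud(25, seed = 5)$points, runif(25))
  write_point_cloud(cl2, f)
  back <- read_point_cloud(f)
  expect_equal(back$points, cl2$points, tolerance = 1e-6)
  expect_equal(back$features, cl2$features, tolerance = 1e-6)
})

test_that("PLY ascii and binary round-trip losslessly", {
  cl <- point_cloud(scatter_cloud(40, seed = 6)$points, runif(40) / 3)
  for (bin in c(FALSE, TRUE)) {
    f <- withr::local_tempfile(fileext = ".ply")
    write_point_cloud(cl, f, binary = bin)
    back <- read_point_cloud(f)
    expect_equal(back$points, cl$points, tolerance = 1e-9)
    expect_equal(back$features, cl$features, tolerance = 1e-9)
  }
})

test_that("PLY with a per-vertex scalar from an independent writer is parsed", {
  # fixture written directly per the PLY spec, not via write_point_cloud
  f <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0",
               "comment hand-built fixture",
               "element vertex 3",
               "property float x", "property float y", "property float z",
               "property float quality",
               "end_header",
               "0 0 0 0.1", "1.5 0 0 0.2", "0 2.5 0 0.3"), f)
  cl <- read_point_cloud(f)
  expect_equal(n_points(cl), 3L)
  expect_equal(cl$features, c(0.1, 0.2, 0.3))
  expect_equal(cl$points[3, ], c(0, 2.5, 0))
})

test_that("PCD ascii round-trips and malformed records are reported", {
  cl <- point_cloud(scatter_cloud(30, seed = 8)$points, runif(30))
  f <- withr::local_tempfile(fileext = ".pcd")
  write_point_cloud(cl, f)
  back <- read_point_cloud(f)
  expect_equal(back$points, cl$points, tolerance = 1e-9)
  expect_equal(back$features, cl$features, tolerance = 1e-9)

  bad <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("0 0 0", "not numbers here"), bad)
  expect_error(read_point_cloud(bad), "line 2")
})

test_that("transform text files round-trip", {
  f <- withr::local_tempfile(fileext = ".txt")
  set.seed(9)
  T1 <- random_rigid()
  write_transform(T1, f)
  back <- read_transform(f)
  expect_equal(transform_matrix(back), transform_matrix(T1), tolerance = 1e-12)
})
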