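# brute-force greedy max-min oracle used to pin FPS behavior
fps_oracle <- function(pts, k, seed_index) {
  n <- nrow(pts)
  chosen <- seed_index
  while (length(chosen) < k) {
    dmin <- sapply(seq_len(n), function(i) {
      min(sqrt(colSums((t(pts[chosen, , drop = FALSE]) - pts[i, ])^2)))
    })
    dmin[chosen] <- -1
    chosen <- c(chosen, which.max(dmin))  # which.max ties -> lowest index
  }
  chosen
}

test_that("farthest point sampling follows greedy max-min with lowest-index ties", {
  line <- point_cloud(cbind(0:9, 0, 0))
  expect_equal(farthest_point_sample(line, 3, seed_index = 1), c(1L, 10L, 5L))

  two <- point_cloud(rbind(c(0, 0, 0), c(1, 1, 1)))
  expect_equal(farthest_point_sample(two, 1), 1L)

  cl <- scatter_cloud(18, seed = 30)
  expect_setequal(farthest_point_sample(cl, 18), 1:18)

  for (s in 1:5) {
    cl <- scatter_cloud(20, seed = 30 + s)
    k <- 7
    expect_equal(farthest_point_sample(cl, k, seed_index = s),
                 as.integer(fps_oracle(cl$points, k, s)))
  }
})

test_that("FPS is permutation-robust for the same geometric seed point", {
  cl <- scatter_cloud(40, seed = 36)
  sel <- farthest_point_sample(cl, 10, seed_index = 3)
  set.seed(37)
  perm <- sample(40)
  shuffled <- point_cloud(cl$points[perm, ])
  sel2 <- farthest_point_sample(shuffled, 10, seed_index = which(perm == 3))
  expect_equal(shuffled$points[sel2, ], cl$points[sel, ])
})

test_that("FPS max-min coverage beats random subsets", {
  cl <- scatter_cloud(80, seed = 38)
  k <- 8
  maxmin <- function(idx) {
    d <- as.matrix(dist(cl$points[idx, ]))
    diag(d) <- Inf
    min(d)
  }
  fps_score <- maxmin(farthest_point_sample(cl, k))
  set.seed(39)
  for (i in 1:50) {
    expect_gte(fps_score, maxmin(sample(80, k)))
  }
})

test_that("extract_regions assigns closed-ball membership identical to brute force", {
  cl <- scatter_cloud(200, seed = 40)
  rs <- extract_regions(cl, k = 5, region_radius = 8)
  for (i in seq_along(rs$regions)) {
    d <- sqrt(colSums((t(cl$points) - rs$sample_points[i, ])^2))
    expect_setequal(rs$regions[[i]], which(d <= 8))
    expect_true(rs$sample_indices[i] %in% rs$regions[[i]])
  }

  # radius >= diameter: every region is the whole cloud
  rs2 <- extract_regions(cl, k = 3, region_radius = 2 * bounding_radius(cl))
  for (r in rs2$regions) expect_setequal(r, seq_len(200))

  # far-away point belongs to no region
  cl3 <- point_cloud(rbind(scatter_cloud(30, seed = 41)$points,
                           c(500, 500, 500)))
  rs3 <- extract_regions(cl3, k = 2, region_radius = 5, seed_index = 1)
  in_any <- unique(unlist(rs3$regions))
  # the isolated point is selected by FPS (it is farthest) so it anchors
  # its own region; membership beyond its ball must still exclude others
  for (i in seq_along(rs3$regions)) {
    d <- sqrt(colSums((t(cl3$points) - rs3$sample_points[i, ])^2))
    expect_setequal(rs3$regions[[i]], which(d <= 5))
  }
})

test_that("region union covers the cloud when FPS spacing is below the radius", {
  cl <- scatter_cloud(150, seed = 42)
  k <- 12
  sel <- farthest_point_sample(cl, k)
  cover <- max(spinereg:::knn_cpp(cl$points,
                                  cl$points[sel, , drop = FALSE],
                                  1L, FALSE)$dist[, 1])
  rs <- extract_regions(cl, k, region_radius = cover + 1e-9)
  expect_setequal(unique(unlist(rs$regions)), seq_len(150))
})

test_that("equalize_density matches the reference spacing within 20 %", {
  ref <- make_phantom(50, 1200)
  expect_identical(equalize_density(ref, ref), ref)

  dense <- make_phantom(51, 6000)  # same surface, ~5x denser
  out <- equalize_density(dense, ref)
  ratio <- median_nn_spacing(out) / median_nn_spacing(ref)
  expect_gte(ratio, 0.8)
  expect_lte(ratio, 1.25)
  expect_lt(n_points(out), n_points(dense))

  single <- point_cloud(matrix(0, 1, 3))
  expect_warning(out2 <- equalize_density(dense, single), "degenerate")
  expect_identical(out2, dense)

  sparse_ref <- make_phantom(52, 600)
  sparse_dense <- make_phantom(53, 650)
  expect_silent(res <- equalize_density(sparse_dense, sparse_ref))
})
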