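test_that("match_keypoints is a row-stochastic softmax with closed-form values", {
  kp <- function(feat) spinereg:::.keypoint_set(matrix(0, nrow(feat), 3), feat)

  # N = 1: trivially [[1]]
  phi1 <- match_keypoints(kp(matrix(1, 1, 2)), kp(matrix(1, 1, 2)), 1)
  expect_equal(phi1$probabilities, matrix(1, 1, 1))

  # identical features: uniform rows
  same <- matrix(rep(c(1, 2), each = 4), 4, 2)
  phiu <- match_keypoints(kp(same), kp(same), 0.5)
  expect_equal(phiu$probabilities, matrix(1 / 4, 4, 4))

  # 2x2 with dot products [[2,0],[0,2]] at T=1: rows are softmax([2,0])
  A <- rbind(c(sqrt(2), 0), c(0, sqrt(2)))
  phi <- match_keypoints(kp(A), kp(A), 1)
  p <- exp(2) / (exp(2) + 1)
  expect_equal(phi$probabilities, rbind(c(p, 1 - p), c(1 - p, p)),
               tolerance = 1e-12)

  # row-stochastic for random features, and column-permutation equivariant
  set.seed(60)
  FX <- matrix(rnorm(40), 8, 5)
  FY <- matrix(rnorm(60), 12, 5)
  phi <- match_keypoints(kp(FX), kp(FY), 0.3)
  expect_equal(rowSums(phi$probabilities), rep(1, 8), tolerance = 1e-6)
  perm <- sample(12)
  phi_p <- match_keypoints(kp(FX), kp(FY[perm, ]), 0.3)
  expect_equal(phi_p$probabilities, phi$probabilities[, perm],
               tolerance = 1e-12)
})

test_that("extract_correspondences equals a brute-force mutual-argmax scan", {
  kp <- function(n) spinereg:::.keypoint_set(matrix(seq_len(3 * n), n, 3),
                                             matrix(0, n, 2))
  mk_phi <- function(P) structure(list(probabilities = P, temperature = 1),
                                  class = "match_matrix")

  # diagonal-dominant: all (i, i)
  P <- diag(8) * 0.9 + 0.1 / 8
  co <- extract_correspondences(mk_phi(P), kp(8), kp(8))
  expect_equal(co$i, 1:8)
  expect_equal(co$j, 1:8)

  # uniform with min_prob above 1/N: empty
  P <- matrix(1 / 6, 6, 6)
  co <- extract_correspondences(mk_phi(P), kp(6), kp(6), min_prob = 0.2)
  expect_equal(nrow(co), 0L)

  # random matrices vs exhaustive oracle
  set.seed(61)
  for (rep in 1:5) {
    P <- matrix(runif(9 * 7), 9, 7)
    P <- P / rowSums(P)
    co <- extract_correspondences(mk_phi(P), kp(9), kp(7), min_prob = 0.1)
    expected <- list()
    for (i in 1:9) {
      j <- which.max(P[i, ])
      if (which.max(P[, j]) == i && P[i, j] >= 0.1) {
        expected[[length(expected) + 1L]] <- c(i, j)
      }
    }
    expected <- do.call(rbind, expected)
    if (is.null(expected)) {
      expect_equal(nrow(co), 0L)
    } else {
      expect_equal(cbind(co$i, co$j), expected)
    }
  }
})

test_that("encode produces the configured keypoint count deterministically", {
  cfg <- tiny_encoder_config()
  model <- init_matcher(cfg, seed = 5)
  cl <- compute_curvature(make_phantom(62, 900), curvature_config())

  kp1 <- encode(cl, model)
  kp2 <- encode(cl, model)
  expect_identical(kp1, kp2)
  expect_equal(nrow(kp1$coords), 48L)  # SA1 n_out
  expect_equal(ncol(kp1$features), 16L)
  expect_true(all(is.finite(kp1$features)))
  # keypoint coordinates are a subset of the input coordinates
  expect_true(all(kp1$coords %in% cl$points))

  small <- subset_cloud(cl, 1:5)  # below SA3 n_out
  expect_error(encode(small, model), "deepest SA layer")
  expect_error(encode(point_cloud(cl$points), model), "curvature")
})

test_that("attend is symmetric, feature-only, and genuinely cross-conditioned", {
  cfg <- tiny_encoder_config()
  model <- init_matcher(cfg, seed = 6)
  clA <- compute_curvature(make_phantom(63, 800), curvature_config())
  clB <- compute_curvature(make_phantom(64, 800), curvature_config())
  A <- encode(clA, model)
  B <- encode(clB, model)

  ab <- attend(A, B, model)
  ba <- attend(B, A, model)
  expect_equal(ab$src$features, ba$tgt$features, tolerance = 1e-12)
  expect_equal(ab$tgt$features, ba$src$features, tolerance = 1e-12)

  expect_identical(ab$src$coords, A$coords)
  expect_identical(ab$tgt$coords, B$coords)

  # cross-dependence: perturbing one target feature row changes f^_X
  B2 <- B
  B2$features[3, ] <- B2$features[3, ] + 0.5
  ab2 <- attend(A, B2, model)
  expect_gt(max(abs(ab2$src$features - ab$src$features)), 1e-8)
})

test_that("hand-derived gradients agree with finite differences", {
  ns <- asNamespace("spinereg")
  cfg <- encoder_config(
    sa_layers = list(list(n_out = 12L, radius = 4, mlp = c(6L, 8L)),
                     list(n_out = 8L, radius = 8, mlp = c(8L, 10L)),
                     list(n_out = 5L, radius = 16, mlp = c(10L, 12L))),
    fp_mlp = c(10L), feature_dim = 8L,
    attention = list(num_heads = 2L, num_blocks = 1L),
    max_neighbors = 8L, batch_points = 40L)
  model <- init_matcher(cfg, 0.05, seed = 7)
  params <- model$params
  # nudge all parameters off zero: exact zeros sit on ReLU/max-pool
  # kinks where one-sided derivatives differ
  set.seed(77)
  params <- ns$.tree_map(function(x) x + rnorm(length(x), sd = 1e-3), params)

  set.seed(1)
  src <- point_cloud(matrix(rnorm(90, sd = 5), 30, 3))
  TG <- rigid_transform(rot_z(20) %*% rot_x(10), c(1, 2, 3))
  tgt <- apply_transform(src, TG)
  tgt$points <- tgt$points + matrix(rnorm(90, sd = 0.3), 30, 3)
  prep <- ns$.prepare_pair(list(src = src, tgt = tgt, T_G = TG), cfg, 3,
                           curvature_config(4, 3))
  expect_gt(nrow(prep$gt_pairs), 3)

  lossfn <- function(p) ns$.pair_forward(prep, p, cfg, 10)$loss
  fwd <- ns$.pair_forward(prep, params, cfg, 10)
  gr <- ns$.pair_backward(fwd$cache, params, cfg, 10)

  check_block <- function(get, set, g) {
    vals <- get(params)
    set.seed(99)
    idx <- sample(length(vals), min(4, length(vals)))
    for (i in idx) {
      eps <- 1e-5
      num <- (lossfn(set(params, i, vals[i] + eps)) -
              lossfn(set(params, i, vals[i] - eps))) / (2 * eps)
      expect_equal(g[i], num, tolerance = 1e-4)
    }
  }
  check_block(function(p) p$encoder$sa[[1]][[1]]$W,
              function(p, i, v) { p$encoder$sa[[1]][[1]]$W[i] <- v; p },
              gr$encoder$sa[[1]][[1]]$W)
  check_block(function(p) p$encoder$sa[[3]][[1]]$b,
              function(p, i, v) { p$encoder$sa[[3]][[1]]$b[i] <- v; p },
              gr$encoder$sa[[3]][[1]]$b)
  check_block(function(p) p$encoder$fp[[2]]$W,
              function(p, i, v) { p$encoder$fp[[2]]$W[i] <- v; p },
              gr$encoder$fp[[2]]$W)
  check_block(function(p) p$attention[[1]]$self$Wq,
              function(p, i, v) { p$attention[[1]]$self$Wq[i] <- v; p },
              gr$attention[[1]]$self$Wq)
  check_block(function(p) p$attention[[1]]$cross$Wv,
              function(p, i, v) { p$attention[[1]]$cross$Wv[i] <- v; p },
              gr$attention[[1]]$cross$Wv)
  check_block(function(p) p$attention[[1]]$ffn[[1]]$W,
              function(p, i, v) { p$attention[[1]]$ffn[[1]]$W[i] <- v; p },
              gr$attention[[1]]$ffn[[1]]$W)
  check_block(function(p) p$log_T,
              function(p, i, v) { p$log_T <- v; p },
              gr$log_T)
})

test_that("training reduces the loss and is bit-reproducible under a fixed seed", {
  fix <- tiny_trained_fixture()
  model <- fix$model
  losses <- model$history$loss
  expect_lt(tail(losses, 1), losses[1])
  # epoch-block averages of the loss are non-increasing
  blocks <- tapply(losses, ceiling(seq_along(losses) / 5), mean)
  expect_true(all(diff(blocks) <= 0.05 * abs(blocks[-length(blocks)])))

  model2 <- train_matcher(fix$training_pairs, encoder_config(),
                          training_config(epochs = 20, batch_size = 2,
                                          learning_rate = 1e-2,
                                          temperature_init = 0.1,
                                          correspondence_radius = 2.5,
                                          seed = 11))
  expect_equal(model2$history$loss, losses, tolerance = 1e-12)
})

test_that("models serialize to versioned JSON and back", {
  fix <- tiny_trained_fixture()
  f <- withr::local_tempfile(fileext = ".json")
  write_model(fix$model, f)
  back <- read_model(f)
  expect_equal(back$params$log_T, fix$model$params$log_T)
  expect_equal(back$params$encoder$sa[[1]][[1]]$W,
               fix$model$params$encoder$sa[[1]][[1]]$W)
  cl <- compute_curvature(make_phantom(70, 800), curvature_config())
  expect_equal(encode(cl, back)$features, encode(cl, fix$model)$features,
               tolerance = 1e-12)
})
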