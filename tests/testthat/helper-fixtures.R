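# Shared fixtures: tiny architectures and a small trained model, built
# once per test run. All sizes are deliberately small; the matcher's
# behavior, not its capacity, is under test.

tiny_encoder_config <- function() {
  encoder_config(
    sa_layers = list(list(n_out = 48L, radius = 3.0, mlp = c(12L, 24L)),
                     list(n_out = 24L, radius = 6.0, mlp = c(24L, 32L)),
                     list(n_out = 12L, radius = 12.0, mlp = c(32L, 32L))),
    fp_mlp = c(32L), feature_dim = 16L,
    attention = list(num_heads = 2L, num_blocks = 1L),
    max_neighbors = 24L, batch_points = 384L)
}

random_rigid <- function() {
  random_transform(170, 50)
}

# small scattered surface-like cloud
scatter_cloud <- function(n, seed, scale = 20) {
  set.seed(seed)
  pts <- matrix(rnorm(3 * n, sd = scale / 2), n, 3L)
  pts[, 3] <- 0.05 * (pts[, 1]^2 - pts[, 2]^2) / scale + rnorm(n, sd = 0.3)
  point_cloud(pts)
}

.fixture_env <- new.env(parent = emptyenv())

# A small trained model plus the pairs it was trained on; built lazily
# and reused by matcher/pipeline/evaluation tests.
tiny_trained_fixture <- function() {
  if (!is.null(.fixture_env$fix)) return(.fixture_env$fix)
  pairs <- lapply(1:12, function(i) {
    make_pair(pair_spec(n_preop = 16384, density_ratio = 2, seed = 400 + i))
  })
  tp <- training_pairs_from_synthetic(pairs)
  model <- train_matcher(tp, encoder_config(),
                         training_config(epochs = 20, batch_size = 2,
                                         learning_rate = 1e-2,
                                         temperature_init = 0.1,
                                         correspondence_radius = 2.5,
                                         seed = 11))
  .fixture_env$fix <- list(pairs = pairs, training_pairs = tp, model = model)
  .fixture_env$fix
}
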