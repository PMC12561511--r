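#' Encoder configuration for the curvature-feature matcher
#'
#' Three set-abstraction (SA) layers, each defined by the number of
#' farthest-point-sampled output points `n_out`, a grouping `radius` in
#' mm, and the widths of its per-point perceptron, followed by one
#' feature-propagation (FP) layer that interpolates the deepest features
#' back onto the first-layer keypoints. Defaults are sized for clouds of
#' a few hundred points covering a ~10-30 mm surface patch.
#'
#' @param sa_layers list of exactly 3 records, each
#'   `list(n_out =, radius =, mlp =)` with strictly decreasing `n_out`.
#' @param fp_mlp hidden widths of the FP perceptron.
#' @param feature_dim output descriptor dimension (>= 8).
#' @param attention `list(num_heads =, num_blocks =)` for the self/cross
#'   graph-attention stage.
#' @param max_neighbors cap on neighbors per SA group (nearest kept).
#' @param batch_points clouds are resampled by FPS to at most this many
#'   points before encoding during training.
#' @export
encoder_config <- function(sa_layers = list(
                             list(n_out = 96L, radius = 3.0, mlp = c(16L, 32L)),
                             list(n_out = 48L, radius = 6.0, mlp = c(32L, 64L)),
                             list(n_out = 24L, radius = 12.0, mlp = c(64L, 64L))),
                           fp_mlp = c(64L),
                           feature_dim = 32L,
                           attention = list(num_heads = 4L, num_blocks = 1L),
                           max_neighbors = 32L,
                           batch_points = 512L) {
  if (length(sa_layers) != 3L) stop("exactly 3 SA layers are required")
  n_outs <- vapply(sa_layers, function(l) as.integer(l$n_out), 1L)
  if (any(diff(n_outs) >= 0L)) stop("SA n_out must be strictly decreasing")
  if (feature_dim < 8L) stop("feature_dim must be >= 8")
  if (feature_dim %% attention$num_heads != 0L) {
    stop("feature_dim must be divisible by the number of attention heads")
  }
  structure(list(sa_layers = sa_layers, fp_mlp = fp_mlp,
                 feature_dim = as.integer(feature_dim),
                 attention = attention,
                 max_neighbors = as.integer(max_neighbors),
                 batch_points = as.integer(batch_points)),
            class = "encoder_config")
}

#' Training configuration
#'
#' Adam with the learning rate halved on a fixed epoch schedule. The
#' matching temperature starts at `temperature_init` and is itself
#' learned. Ground-truth correspondences for the loss are keypoint pairs
#' within `correspondence_radius` mm under the ground-truth transform.
#'
#' @param learning_rate initial Adam step size.
#' @param lr_halving_epochs halve the learning rate every this many
#'   epochs.
#' @param batch_size pairs per gradient step.
#' @param epochs training epochs.
#' @param temperature_init initial softmax temperature.
#' @param loss_scale scale applied to the matching loss.
#' @param correspondence_radius mm radius defining ground-truth matches.
#' @param seed integer driving weight init, batching order and any
#'   sampling.
#' @export
training_config <- function(learning_rate = 1e-4, lr_halving_epochs = 5L,
                            batch_size = 4L, epochs = 100L,
                            temperature_init = 1e-2, loss_scale = 10,
                            correspondence_radius = 10, seed = 1L) {
  vals <- c(learning_rate, lr_halving_epochs, batch_size, epochs,
            temperature_init, loss_scale, correspondence_radius)
  if (any(vals <= 0)) stop("all training_config values must be positive")
  structure(list(learning_rate = learning_rate,
                 lr_halving_epochs = as.integer(lr_halving_epochs),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 temperature_init = temperature_init,
                 loss_scale = loss_scale,
                 correspondence_radius = correspondence_radius,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Initialize an untrained matcher model
#'
#' @param enc_cfg an [encoder_config()].
#' @param temperature_init initial softmax temperature.
#' @param seed RNG seed for the weight initialization.
#' @return A `matcher_model`.
#' @export
init_matcher <- function(enc_cfg = encoder_config(), temperature_init = 1e-2,
                         seed = 1L) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  params <- list(encoder = .encoder_init(enc_cfg),
                 attention = .attention_init(enc_cfg),
                 log_T = log(temperature_init))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  structure(list(schema_version = 1L, config = enc_cfg, params = params,
                 trained = FALSE, history = NULL),
            class = "matcher_model")
}

#' @export
print.matcher_model <- function(x, ...) {
  cat(sprintf("<matcher_model> d=%d, %s, T=%.4g\n", x$config$feature_dim,
              if (x$trained) sprintf("trained (%d epochs)",
                                     length(x$history$loss)) else "untrained",
              exp(x$params$log_T)))
  invisible(x)
}

#' Temperature of a matcher model
#' @param model a `matcher_model`.
#' @export
model_temperature <- function(model) exp(model$params$log_T)

.keypoint_set <- function(coords, features) {
  structure(list(coords = coords, features = features),
            class = "keypoint_set")
}

#' @export
print.keypoint_set <- function(x, ...) {
  cat(sprintf("<keypoint_set> %d keypoints, %d-dim features\n",
              nrow(x$coords), ncol(x$features)))
  invisible(x)
}

.resample_cloud <- function(cloud, n_max) {
  if (n_points(cloud) <= n_max) return(cloud)
  subset_cloud(cloud, farthest_point_sample(cloud, n_max))
}

#' Encode a cloud into keypoints with local descriptors
#'
#' Runs the SA/FP encoder on a curvature-annotated cloud. Keypoint
#' coordinates are the first SA layer's farthest-point samples (a subset
#' of the input coordinates); features are the FP output, prior to
#' attention.
#'
#' @param cloud a [point_cloud()] with curvature features (see
#'   [compute_curvature()]).
#' @param model a `matcher_model` (its config defines the architecture).
#' @param resample resample the cloud to `batch_points` by FPS first.
#' @return A `keypoint_set` with `coords` (N x 3) and `features` (N x d).
#' @export
encode <- function(cloud, model, resample = TRUE) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(model, "matcher_model"))
  if (is.null(cloud$features)) {
    stop("cloud has no curvature features; run compute_curvature() first")
  }
  cfg <- model$config
  if (n_points(cloud) < cfg$sa_layers[[3]]$n_out) {
    stop("cloud smaller than the deepest SA layer's output count")
  }
  if (resample) cloud <- .resample_cloud(cloud, cfg$batch_points)
  enc <- .encoder_fwd(cloud$points, cloud$features, cfg, model$params$encoder)
  .keypoint_set(enc$coords, enc$features)
}

#' Contextualize two keypoint sets with self/cross attention
#'
#' Updates both feature sets through the model's graph-attention blocks
#' (self-attention within each cloud, cross-attention between them,
#' parallel updates so the operation is symmetric in its arguments) and
#' L2-normalizes the rows. Coordinates are untouched.
#'
#' @param src,tgt `keypoint_set`s from [encode()].
#' @param model a `matcher_model`.
#' @return `list(src =, tgt =)` of updated `keypoint_set`s.
#' @export
attend <- function(src, tgt, model) {
  stopifnot(inherits(src, "keypoint_set"), inherits(tgt, "keypoint_set"))
  att <- .attention_fwd(src$features, tgt$features, model$params$attention,
                        model$config$attention$num_heads)
  fx <- .featnorm_fwd(att$FX)$out
  fy <- .featnorm_fwd(att$FY)$out
  list(src = .keypoint_set(src$coords, fx),
       tgt = .keypoint_set(tgt$coords, fy))
}

#' Soft correspondence matrix between two keypoint sets
#'
#' Row-wise softmax of the scaled feature similarity
#' `phi = softmax(f_X f_Y' / T)`: row `i` is the matching distribution
#' of source keypoint `i` over all target keypoints.
#'
#' @param src,tgt `keypoint_set`s with equal feature dimension (usually
#'   the output of [attend()]).
#' @param temperature softmax temperature `T > 0`.
#' @return A `match_matrix`: list with `probabilities` (N x M, rows sum
#'   to 1) and `temperature`.
#' @export
match_keypoints <- function(src, tgt, temperature) {
  stopifnot(inherits(src, "keypoint_set"), inherits(tgt, "keypoint_set"),
            ncol(src$features) == ncol(tgt$features), temperature > 0)
  S <- src$features %*% t(tgt$features) / temperature
  S <- sweep(S, 1L, apply(S, 1L, max), "-")
  P <- exp(S)
  P <- P / rowSums(P)
  structure(list(probabilities = P, temperature = temperature),
            class = "match_matrix")
}

#' @export
print.match_matrix <- function(x, ...) {
  cat(sprintf("<match_matrix> %d x %d, T=%.4g\n", nrow(x$probabilities),
              ncol(x$probabilities), x$temperature))
  invisible(x)
}

#' Extract mutual-argmax correspondences from a match matrix
#'
#' Keeps pair `(i, j)` when `j` is the argmax of row `i`, `i` is the
#' argmax of column `j` (mutual consistency), and the probability is at
#' least `min_prob`. Argmax ties break to the lowest index. May return
#' zero rows.
#'
#' @param phi a `match_matrix`.
#' @param src,tgt the corresponding `keypoint_set`s.
#' @param min_prob minimum row probability to keep a pair.
#' @return data.frame with columns `i`, `j`, `prob` and attached
#'   coordinate matrices in attributes `src_xyz`, `tgt_xyz`.
#' @export
extract_correspondences <- function(phi, src, tgt, min_prob = 0) {
  P <- phi$probabilities
  row_arg <- apply(P, 1L, which.max)  # which.max: first (lowest) index on ties
  col_arg <- apply(P, 2L, which.max)
  i <- seq_len(nrow(P))
  j <- row_arg
  keep <- col_arg[j] == i & P[cbind(i, j)] >= min_prob
  out <- data.frame(i = i[keep], j = j[keep], prob = P[cbind(i, j)][keep])
  attr(out, "src_xyz") <- src$coords[out$i, , drop = FALSE]
  attr(out, "tgt_xyz") <- tgt$coords[out$j, , drop = FALSE]
  out
}

# Full differentiable forward pass for one training pair. Returns the
# loss and all caches needed for the backward sweep.
.pair_forward <- function(prep, params, cfg, loss_scale) {
  ex <- .encoder_fwd(prep$src_pts, prep$src_curv, cfg, params$encoder)
  ey <- .encoder_fwd(prep$tgt_pts, prep$tgt_curv, cfg, params$encoder)
  att <- .attention_fwd(ex$features, ey$features, params$attention,
                        cfg$attention$num_heads)
  nx <- .featnorm_fwd(att$FX)
  ny <- .featnorm_fwd(att$FY)
  Tm <- exp(params$log_T)
  logits <- nx$out %*% t(ny$out) / Tm
  lx <- sweep(logits, 1L, apply(logits, 1L, max), "-")
  PX <- exp(lx); PX <- PX / rowSums(PX)
  ly <- sweep(t(logits), 1L, apply(logits, 2L, max), "-")
  PY <- exp(ly); PY <- PY / rowSums(PY)
  M <- prep$gt_pairs  # two-column matrix (i, j) on keypoint indices
  if (nrow(M) == 0L) return(list(loss = NA_real_, skip = TRUE))
  nm <- nrow(M)
  loss <- -(mean(log(pmax(PX[M], 1e-300))) +
            mean(log(pmax(PY[M[, c(2, 1), drop = FALSE]], 1e-300)))) / 2
  loss <- loss * loss_scale
  list(loss = loss, skip = FALSE,
       cache = list(ex = ex, ey = ey, att = att, nx = nx, ny = ny,
                    PX = PX, PY = PY, logits = logits, Tm = Tm, M = M,
                    nm = nm))
}

.pair_backward <- function(cc, params, cfg, loss_scale) {
  dlx <- matrix(0, nrow(cc$PX), ncol(cc$PX))
  dly <- matrix(0, ncol(cc$PX), nrow(cc$PX))
  for (m in seq_len(cc$nm)) {
    i <- cc$M[m, 1L]; j <- cc$M[m, 2L]
    dlx[i, ] <- dlx[i, ] + cc$PX[i, ] / cc$nm
    dlx[i, j] <- dlx[i, j] - 1 / cc$nm
    dly[j, ] <- dly[j, ] + cc$PY[j, ] / cc$nm
    dly[j, i] <- dly[j, i] - 1 / cc$nm
  }
  dlogits <- (dlx + t(dly)) / 2 * loss_scale
  dFXn <- dlogits %*% cc$ny$out / cc$Tm
  dFYn <- t(dlogits) %*% cc$nx$out / cc$Tm
  dlogT <- -sum(dlogits * cc$logits)  # d/dlogT since logits ~ 1/T
  dFX <- .featnorm_bwd(dFXn, cc$nx$out, cc$nx$nrm)
  dFY <- .featnorm_bwd(dFYn, cc$ny$out, cc$ny$nrm)
  ab <- .attention_bwd(dFX, dFY, cc$att$caches, params$attention,
                       cfg$attention$num_heads)
  gx <- .encoder_bwd(ab$dFX, cc$ex$cache, cfg, params$encoder)
  gy <- .encoder_bwd(ab$dFY, cc$ey$cache, cfg, params$encoder)
  enc_grads <- .tree_map(`+`, gx$grads, gy$grads)
  list(encoder = enc_grads, attention = ab$grads, log_T = dlogT)
}

# Resample, annotate and pre-pair one training example. Keypoints are
# deterministic given the resampled coordinates, so ground-truth keypoint
# correspondences can be frozen once.
.prepare_pair <- function(pair, cfg, corr_radius, curv_cfg) {
  src <- pair$src
  tgt <- pair$tgt
  if (is.null(src$features)) src <- compute_curvature(src, curv_cfg)
  if (is.null(tgt$features)) tgt <- compute_curvature(tgt, curv_cfg)
  src <- .resample_cloud(src, cfg$batch_points)
  tgt <- .resample_cloud(tgt, cfg$batch_points)
  kx <- min(cfg$sa_layers[[1]]$n_out, n_points(src))
  ky <- min(cfg$sa_layers[[1]]$n_out, n_points(tgt))
  kp_x <- src$points[as.integer(fps_cpp(src$points, kx, 1L)), , drop = FALSE]
  kp_y <- tgt$points[as.integer(fps_cpp(tgt$points, ky, 1L)), , drop = FALSE]
  moved <- sweep(kp_x %*% t(pair$T_G$rotation), 2L, pair$T_G$translation, "+")
  hits <- radius_groups_cpp(moved, kp_y, corr_radius, 0L)
  gt <- do.call(rbind, lapply(seq_along(hits$index), function(i) {
    js <- hits$index[[i]]
    if (length(js) == 0L) return(NULL)
    cbind(i, as.integer(js))
  }))
  if (is.null(gt)) gt <- matrix(integer(), 0L, 2L)
  list(src_pts = src$points, src_curv = src$features,
       tgt_pts = tgt$points, tgt_curv = tgt$features,
       gt_pairs = gt)
}

#' Train the matcher on registration pairs with ground truth
#'
#' Minimizes the symmetric negative log-likelihood of ground-truth
#' keypoint correspondences (keypoint pairs within
#' `correspondence_radius` mm under each pair's ground-truth transform)
#' with Adam; the learning rate halves every `lr_halving_epochs` epochs
#' and the temperature is learned jointly. Fully reproducible given
#' `tr_cfg$seed`.
#'
#' @param dataset list of `list(src =, tgt =, T_G =)`: source cloud,
#'   target cloud (curvature computed on the fly when absent) and the
#'   ground-truth `rigid_transform` mapping src into tgt's frame.
#' @param enc_cfg an [encoder_config()].
#' @param tr_cfg a [training_config()].
#' @param curv_cfg curvature settings used when a cloud arrives without
#'   features.
#' @param verbose print per-epoch loss.
#' @return A trained `matcher_model` with `history$loss` per epoch.
#' @export
train_matcher <- function(dataset, enc_cfg = encoder_config(),
                          tr_cfg = training_config(),
                          curv_cfg = curvature_config(), verbose = FALSE) {
  if (length(dataset) == 0L) stop("dataset is empty")
  model <- init_matcher(enc_cfg, tr_cfg$temperature_init, tr_cfg$seed)
  params <- model$params
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(tr_cfg$seed + 1L)
  preps <- lapply(dataset, .prepare_pair, cfg = enc_cfg,
                  corr_radius = tr_cfg$correspondence_radius,
                  curv_cfg = curv_cfg)
  n_gt <- vapply(preps, function(p) nrow(p$gt_pairs), 1L)
  if (all(n_gt == 0L)) {
    stop("no training pair has any ground-truth correspondence within ",
         tr_cfg$correspondence_radius, " mm")
  }
  usable <- which(n_gt > 0L)
  state <- list(t = 0L, m = .tree_zeros(params), v = .tree_zeros(params))
  losses <- numeric(tr_cfg$epochs)
  for (epoch in seq_len(tr_cfg$epochs)) {
    lr <- tr_cfg$learning_rate *
      0.5^((epoch - 1L) %/% tr_cfg$lr_halving_epochs)
    order <- sample(usable)
    batches <- split(order, ceiling(seq_along(order) / tr_cfg$batch_size))
    ep_loss <- 0
    for (batch in batches) {
      grads <- NULL
      bl <- 0
      for (pi in batch) {
        fwd <- .pair_forward(preps[[pi]], params, enc_cfg, tr_cfg$loss_scale)
        if (fwd$skip) next
        bl <- bl + fwd$loss
        g <- .pair_backward(fwd$cache, params, enc_cfg, tr_cfg$loss_scale)
        grads <- if (is.null(grads)) g else .tree_map(`+`, grads, g)
      }
      if (is.null(grads)) next
      grads <- .tree_map(function(g) g / length(batch), grads)
      upd <- .adam_step(params, grads, state, lr)
      params <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + bl
    }
    losses[epoch] <- ep_loss / length(usable)
    if (verbose) {
      message(sprintf("epoch %3d  lr %.2e  loss %.4f", epoch, lr,
                      losses[epoch]))
    }
  }
  model$params <- params
  model$trained <- TRUE
  model$history <- list(loss = losses)
  model
}

#' Save / load a matcher model as schema-versioned JSON
#'
#' @param model a `matcher_model`.
#' @param path file path (JSON).
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "matcher_model"))
  payload <- list(schema_version = model$schema_version,
                  config = unclass(model$config),
                  trained = model$trained,
                  history = model$history,
                  params = model$params)
  jsonlite::write_json(jsonlite::serializeJSON(payload, digits = NA),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  payload <- jsonlite::unserializeJSON(jsonlite::read_json(path)[[1]])
  if (is.null(payload$schema_version) || payload$schema_version != 1L) {
    stop("unsupported model schema version")
  }
  cfg <- payload$config
  class(cfg) <- "encoder_config"
  structure(list(schema_version = payload$schema_version, config = cfg,
                 params = payload$params, trained = payload$trained,
                 history = payload$history),
            class = "matcher_model")
}

#' Build training examples from synthetic pairs
#'
#' Converts registration pairs into matcher training examples the way
#' the pipeline consumes them at test time: the intra-operative cloud is
#' density-equalized against the pre-operative cloud, curvature is
#' computed on the full clouds, and the pre-operative side is cropped to
#' a ball around the true overlap (comparable in extent to the candidate
#' regions the matcher will face), so that ground-truth keypoint
#' correspondences actually exist at 1-4 % overlap.
#'
#' @param pairs list of `synthetic_pair`s.
#' @param crop_factor crop radii as multiples of the intra-operative
#'   cloud's bounding radius; several values yield several training
#'   examples per pair, so the matcher sees both tight and region-sized
#'   context (candidate regions at test time are larger than the true
#'   overlap).
#' @param curv_cfg a [curvature_config()].
#' @return list of `list(src =, tgt =, T_G =)` ready for
#'   [train_matcher()].
#' @export
training_pairs_from_synthetic <- function(pairs, crop_factor = c(1.3, 2.2),
                                          curv_cfg = curvature_config()) {
  out <- list()
  for (pair in pairs) {
    preop <- compute_curvature(pair$preop, curv_cfg)
    intraop <- equalize_density(pair$intraop, preop)
    intraop <- compute_curvature(intraop, curv_cfg)
    moved <- apply_transform(intraop, pair$ground_truth)
    ctr <- colMeans(moved$points)
    d <- sqrt(rowSums(sweep(preop$points, 2L, ctr)^2))
    for (cf in crop_factor) {
      keep <- which(d <= cf * bounding_radius(moved))
      out[[length(out) + 1L]] <- list(src = intraop,
                                      tgt = subset_cloud(preop, keep),
                                      T_G = pair$ground_truth)
    }
  }
  out
}
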