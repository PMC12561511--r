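# Internal neural-network machinery for the curvature-feature matcher:
# a hierarchical set-abstraction (SA) encoder with one feature-propagation
# (FP) layer, self/cross multi-head attention, and hand-derived backward
# passes (verified against finite differences in the test suite). All
# local geometry enters as rotation-invariant quantities (radial offset
# to the SA center plus the previous layer's features), so descriptors
# do not depend on the initial pose of either cloud.

.relu <- function(x) pmax(x, 0)

.rand_mat <- function(nr, nc) {
  # scaled Gaussian init (He-style for the ReLU stacks)
  matrix(rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
}

.init_mlp <- function(dims) {
  lapply(seq_len(length(dims) - 1L), function(j) {
    list(W = .rand_mat(dims[j], dims[j + 1L]), b = rep(0, dims[j + 1L]))
  })
}

.mlp_fwd <- function(X, layers, final_linear = FALSE) {
  acts <- list(X)
  zs <- list()
  H <- X
  nl <- length(layers)
  for (j in seq_len(nl)) {
    Z <- H %*% layers[[j]]$W
    Z <- sweep(Z, 2L, layers[[j]]$b, "+")
    zs[[j]] <- Z
    H <- if (final_linear && j == nl) Z else .relu(Z)
    acts[[j + 1L]] <- H
  }
  list(out = H, acts = acts, zs = zs)
}

.mlp_bwd <- function(dout, cache, layers, final_linear = FALSE) {
  nl <- length(layers)
  grads <- vector("list", nl)
  dH <- dout
  for (j in rev(seq_len(nl))) {
    dZ <- if (final_linear && j == nl) dH else dH * (cache$zs[[j]] > 0)
    grads[[j]] <- list(W = crossprod(cache$acts[[j]], dZ), b = colSums(dZ))
    dH <- dZ %*% t(layers[[j]]$W)
  }
  list(dX = dH, grads = grads)
}

# ---- set-abstraction encoder ------------------------------------------

.encoder_init <- function(cfg) {
  sa <- vector("list", 3L)
  in_dim <- 2L  # radial offset + curvature
  for (l in 1:3) {
    dims <- c(in_dim, cfg$sa_layers[[l]]$mlp)
    sa[[l]] <- .init_mlp(dims)
    in_dim <- 1L + cfg$sa_layers[[l]]$mlp[length(cfg$sa_layers[[l]]$mlp)]
  }
  c1 <- tail(cfg$sa_layers[[1]]$mlp, 1L)
  c3 <- tail(cfg$sa_layers[[3]]$mlp, 1L)
  fp <- .init_mlp(c(c1 + c3, cfg$fp_mlp, cfg$feature_dim))
  list(sa = sa, fp = fp)
}

.sa_fwd <- function(pts, feats, layer_cfg, layers, max_k) {
  n <- nrow(pts)
  k <- min(layer_cfg$n_out, n)
  ctr_idx <- as.integer(fps_cpp(pts, k, 1L))
  ctrs <- pts[ctr_idx, , drop = FALSE]
  grp <- radius_groups_cpp(ctrs, pts, layer_cfg$radius, max_k)
  I <- unlist(grp$index, use.names = FALSE)
  gid <- rep.int(seq_len(k), lengths(grp$index))
  dists <- unlist(grp$dist, use.names = FALSE)
  Xin <- cbind(dists, feats[I, , drop = FALSE])
  mlp <- .mlp_fwd(Xin, layers)
  gm <- group_max_cpp(mlp$out, gid, k)
  list(pts = ctrs, feats = gm$max,
       cache = list(ctr_idx = ctr_idx, I = I, n_prev = n,
                    mlp = mlp, argmax = gm$argmax,
                    S = nrow(Xin), C = ncol(mlp$out)))
}

.sa_bwd <- function(dfeats, cache, layers, want_input_grad) {
  # route gradients through the per-channel max pool
  dH <- matrix(0, cache$S, cache$C)
  idx <- cbind(as.vector(cache$argmax),
               rep(seq_len(cache$C), each = nrow(cache$argmax)))
  dH[idx] <- as.vector(dfeats)
  bwd <- .mlp_bwd(dH, cache$mlp, layers)
  dprev <- NULL
  if (want_input_grad) {
    dXf <- bwd$dX[, -1L, drop = FALSE]  # drop the radial-offset column
    rs <- rowsum(dXf, cache$I)
    dprev <- matrix(0, cache$n_prev, ncol(dXf))
    dprev[as.integer(rownames(rs)), ] <- rs
  }
  list(dprev = dprev, grads = bwd$grads)
}

.encoder_fwd <- function(pts, curv, cfg, params) {
  feats <- matrix(3 * curv, ncol = 1L)  # sigma in [0, 1/3] -> unit scale
  levels <- vector("list", 3L)
  p <- pts
  f <- feats
  for (l in 1:3) {
    levels[[l]] <- .sa_fwd(p, f, cfg$sa_layers[[l]], params$sa[[l]],
                           cfg$max_neighbors)
    p <- levels[[l]]$pts
    f <- levels[[l]]$feats
  }
  # interpolate SA3 features back onto the SA1 keypoints
  kp <- levels[[1]]$pts
  n3 <- nrow(levels[[3]]$pts)
  kk <- min(3L, n3)
  nn <- knn_cpp(kp, levels[[3]]$pts, kk, FALSE)
  w <- 1 / (nn$dist^2 + 1e-8)
  w <- w / rowSums(w)
  interp <- matrix(0, nrow(kp), ncol(levels[[3]]$feats))
  for (q in seq_len(kk)) {
    interp <- interp + levels[[3]]$feats[nn$index[, q], , drop = FALSE] * w[, q]
  }
  Xfp <- cbind(levels[[1]]$feats, interp)
  fp <- .mlp_fwd(Xfp, params$fp, final_linear = TRUE)
  list(coords = kp, features = fp$out,
       cache = list(levels = levels, nn_idx = nn$index, w = w, kk = kk,
                    n3 = n3, c3 = ncol(levels[[3]]$feats), fp = fp))
}

.encoder_bwd <- function(dfeat, cache, cfg, params) {
  fp_bwd <- .mlp_bwd(dfeat, cache$fp, params$fp, final_linear = TRUE)
  c1 <- ncol(cache$levels[[1]]$feats)
  df1 <- fp_bwd$dX[, seq_len(c1), drop = FALSE]
  dinterp <- fp_bwd$dX[, -seq_len(c1), drop = FALSE]
  df3 <- matrix(0, cache$n3, cache$c3)
  for (q in seq_len(cache$kk)) {
    rs <- rowsum(dinterp * cache$w[, q], cache$nn_idx[, q])
    ridx <- as.integer(rownames(rs))
    df3[ridx, ] <- df3[ridx, , drop = FALSE] + rs
  }
  b3 <- .sa_bwd(df3, cache$levels[[3]]$cache, params$sa[[3]], TRUE)
  b2 <- .sa_bwd(b3$dprev, cache$levels[[2]]$cache, params$sa[[2]], TRUE)
  df1 <- df1 + b2$dprev
  b1 <- .sa_bwd(df1, cache$levels[[1]]$cache, params$sa[[1]], FALSE)
  list(grads = list(sa = list(b1$grads, b2$grads, b3$grads),
                    fp = fp_bwd$grads))
}

# ---- multi-head attention ---------------------------------------------

.att_weights_init <- function(d) {
  list(Wq = .rand_mat(d, d), Wk = .rand_mat(d, d),
       Wv = .rand_mat(d, d), Wo = .rand_mat(d, d))
}

.attention_init <- function(cfg) {
  d <- cfg$feature_dim
  lapply(seq_len(cfg$attention$num_blocks), function(b) {
    list(self = .att_weights_init(d), cross = .att_weights_init(d),
         ffn = .init_mlp(c(d, 2L * d, d)))
  })
}

.mha_fwd <- function(Fq, Fkv, w, nh) {
  d <- ncol(Fq)
  dh <- d %/% nh
  Q <- Fq %*% w$Wq
  K <- Fkv %*% w$Wk
  V <- Fkv %*% w$Wv
  heads <- vector("list", nh)
  Ocat <- matrix(0, nrow(Fq), d)
  for (h in seq_len(nh)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    S <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dh)
    S <- sweep(S, 1L, apply(S, 1L, max), "-")
    A <- exp(S)
    A <- A / rowSums(A)
    Ocat[, cols] <- A %*% V[, cols, drop = FALSE]
    heads[[h]] <- A
  }
  out <- Ocat %*% w$Wo
  list(out = out, cache = list(Fq = Fq, Fkv = Fkv, Q = Q, K = K, V = V,
                               heads = heads, Ocat = Ocat, nh = nh, dh = dh))
}

.mha_bwd <- function(dout, cache, w) {
  nh <- cache$nh
  dh <- cache$dh
  dWo <- crossprod(cache$Ocat, dout)
  dOcat <- dout %*% t(w$Wo)
  dQ <- matrix(0, nrow(cache$Q), ncol(cache$Q))
  dK <- matrix(0, nrow(cache$K), ncol(cache$K))
  dV <- matrix(0, nrow(cache$V), ncol(cache$V))
  for (h in seq_len(nh)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    A <- cache$heads[[h]]
    dOh <- dOcat[, cols, drop = FALSE]
    dA <- dOh %*% t(cache$V[, cols, drop = FALSE])
    dV[, cols] <- crossprod(A, dOh)
    dS <- A * (dA - rowSums(A * dA))
    dQ[, cols] <- dS %*% cache$K[, cols, drop = FALSE] / sqrt(dh)
    dK[, cols] <- crossprod(dS, cache$Q[, cols, drop = FALSE]) / sqrt(dh)
  }
  list(dFq = dQ %*% t(w$Wq),
       dFkv = dK %*% t(w$Wk) + dV %*% t(w$Wv),
       grads = list(Wq = crossprod(cache$Fq, dQ),
                    Wk = crossprod(cache$Fkv, dK),
                    Wv = crossprod(cache$Fkv, dV),
                    Wo = dWo))
}

.attention_fwd <- function(FX, FY, blocks, nh) {
  caches <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    p <- blocks[[b]]
    sx <- .mha_fwd(FX, FX, p$self, nh)
    sy <- .mha_fwd(FY, FY, p$self, nh)
    FX1 <- FX + sx$out
    FY1 <- FY + sy$out
    # parallel cross update keeps attend() symmetric in its arguments
    cx <- .mha_fwd(FX1, FY1, p$cross, nh)
    cy <- .mha_fwd(FY1, FX1, p$cross, nh)
    FX2 <- FX1 + cx$out
    FY2 <- FY1 + cy$out
    fx <- .mlp_fwd(FX2, p$ffn, final_linear = TRUE)
    fy <- .mlp_fwd(FY2, p$ffn, final_linear = TRUE)
    FX <- FX2 + fx$out
    FY <- FY2 + fy$out
    caches[[b]] <- list(sx = sx, sy = sy, cx = cx, cy = cy, fx = fx, fy = fy)
  }
  list(FX = FX, FY = FY, caches = caches)
}

.attention_bwd <- function(dFX, dFY, caches, blocks, nh) {
  grads <- vector("list", length(blocks))
  for (b in rev(seq_along(blocks))) {
    p <- blocks[[b]]
    cc <- caches[[b]]
    fxb <- .mlp_bwd(dFX, cc$fx, p$ffn, final_linear = TRUE)
    fyb <- .mlp_bwd(dFY, cc$fy, p$ffn, final_linear = TRUE)
    dFX2 <- dFX + fxb$dX
    dFY2 <- dFY + fyb$dX
    cxb <- .mha_bwd(dFX2, cc$cx$cache, p$cross)
    cyb <- .mha_bwd(dFY2, cc$cy$cache, p$cross)
    dFX1 <- dFX2 + cxb$dFq + cyb$dFkv
    dFY1 <- dFY2 + cyb$dFq + cxb$dFkv
    sxb <- .mha_bwd(dFX1, cc$sx$cache, p$self)
    syb <- .mha_bwd(dFY1, cc$sy$cache, p$self)
    dFX <- dFX1 + sxb$dFq + sxb$dFkv
    dFY <- dFY1 + syb$dFq + syb$dFkv
    grads[[b]] <- list(
      self = Map(`+`, sxb$grads, syb$grads),
      cross = Map(`+`, cxb$grads, cyb$grads),
      ffn = Map(function(a, b) Map(`+`, a, b), fxb$grads, fyb$grads))
  }
  list(dFX = dFX, dFY = dFY, grads = grads)
}

# ---- descriptor normalization -----------------------------------------
# Center features across keypoints, then L2-normalize each row. The
# centering removes the shared feature component; without it a fully
# collapsed feature set (all rows equal) is an exact stationary point of
# the matching loss and training can die there.

.featnorm_fwd <- function(F) {
  mu <- colMeans(F)
  G <- sweep(F, 2L, mu)
  nrm <- sqrt(rowSums(G^2))
  nrm <- pmax(nrm, 1e-12)
  list(out = G / nrm, nrm = nrm)
}

.featnorm_bwd <- function(dout, out, nrm) {
  dG <- (dout - out * rowSums(out * dout)) / nrm
  sweep(dG, 2L, colMeans(dG))
}

# ---- parameter-tree utilities (Adam) ----------------------------------

.tree_map <- function(f, ...) {
  trees <- list(...)
  if (is.list(trees[[1]])) {
    out <- vector("list", length(trees[[1]]))
    names(out) <- names(trees[[1]])
    for (i in seq_along(out)) {
      out[[i]] <- do.call(.tree_map, c(list(f), lapply(trees, `[[`, i)))
    }
    out
  } else {
    do.call(f, trees)
  }
}

.tree_zeros <- function(tree) .tree_map(function(x) x * 0, tree)

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- .tree_map(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- .tree_map(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- .tree_map(function(p, m, v) {
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }, params, state$m, state$v)
  list(params = params, state = state)
}
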