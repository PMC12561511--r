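# Synthetic vertebra-phantom generator. The phantom is a single
# star-shaped radial surface r(u) over the unit sphere: an ellipsoidal
# "body" base modulated by smooth directional bumps — a long, blade-like
# "spinous process" with two off-axis tubercles near its tip and two
# lateral "transverse processes" — plus a fine multiplicative relief
# tied to spatial position. A single implicit sheet has no seams or
# double layers, so two independent samplings of it are geometrically
# consistent, which is what cross-source registration assumes. The
# blade anisotropy, tubercles and relief break the rotational symmetry
# of the exposed tip patch; without them the patch pose would be
# underdetermined about the process axis, which real vertebral anatomy
# never is. Deliberately parametric rather than anatomical: what
# matters downstream is the statistical structure (a curvature-rich
# protrusion, density mismatch, tiny overlap, large pose, noise).

.phantom_axis_spinous <- c(0, -1, 0)

# Gaussian bump in the angle between direction u and a bump axis.
.bump <- function(u, axis, amp, width) {
  ct <- pmin(1, pmax(-1, u %*% axis))
  theta <- acos(ct)
  amp * exp(-(theta / width)^2)
}

# Radius (mm) of the phantom surface in directions u (n x 3 unit rows).
.phantom_radius <- function(u) {
  ax <- c(20, 14, 11)
  base <- 1 / sqrt((u[, 1] / ax[1])^2 + (u[, 2] / ax[2])^2 +
                   (u[, 3] / ax[3])^2)
  # blade-like spinous process: narrower in x than in z, and
  # azimuthally asymmetric — a mirror-symmetric blade would leave
  # flank patches with an ambiguous 180-degree flip
  phi <- atan2(u[, 3], u[, 1])
  w_sp <- 0.16 + 0.10 * sin(phi)^2 + 0.04 * sin(phi) + 0.03 * cos(phi)
  b <- .bump_aniso(u, .phantom_axis_spinous, 1.65, w_sp) +
    .bump(u, c(0.13, -0.98, 0.12), 0.30, 0.07) +   # tubercle on the tip
    .bump(u, c(-0.09, -0.98, -0.15), 0.22, 0.06) + # second tip tubercle
    .bump(u, c(0.28, -0.93, 0.25), 0.33, 0.10) +   # tubercle below tip
    .bump(u, c(1, -0.15, 0), 0.75, 0.22) +         # transverse process
    .bump(u, c(-1, -0.15, 0), 0.75, 0.22)
  r1 <- base * (1 + b)
  # positional relief (~1 mm, ~3-4 mm wavelength) evaluated at the
  # pre-relief surface point so it varies across the small tip patch;
  # this roughness is what pins the patch pose for the fine stage
  p1 <- u * r1
  h <- sin(1.8 * p1[, 1] + 1.3) * sin(1.5 * p1[, 2] + 0.7) +
    0.5 * sin(2.1 * p1[, 3] + 2.1) * sin(1.7 * p1[, 1] - 0.4)
  r1 * (1 + 0.028 * h)
}

.bump_aniso <- function(u, axis, amp, width) {
  ct <- pmin(1, pmax(-1, u %*% axis))
  theta <- acos(ct)
  amp * exp(-(theta / width)^2)
}

# The spinous process tip (anchor region of the exposed patch).
.phantom_tip <- function() {
  u <- matrix(.phantom_axis_spinous, 1L, 3L)
  as.numeric(u * .phantom_radius(u))
}

# Draw n surface points with the current RNG state: directions uniform
# on the sphere, accepted with probability proportional to r(u)^2 (the
# dominant term of the area element; the slant term is smooth and
# identical for every sampling of the surface, so cross-source
# consistency is exact). Normals are approximated by the radial
# direction — they are used only for visibility culling. When `axis`
# and `theta_max` are given, directions are drawn uniformly from the
# spherical cap about `axis` instead (identical law restricted to the
# cap; used to sample the small exposed patch efficiently).
.phantom_draw <- function(n, axis = NULL, theta_max = NULL) {
  r_cap <- 42  # r(u) never exceeds this
  pts <- matrix(NA_real_, 0L, 3L)
  nrm <- matrix(NA_real_, 0L, 3L)
  basis <- if (!is.null(axis)) {
    a <- axis / sqrt(sum(axis^2))
    e1 <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- e1 - sum(e1 * a) * a
    e1 <- e1 / sqrt(sum(e1^2))
    rbind(e1, .cross3(a, e1), a)
  }
  while (nrow(pts) < n) {
    draw <- max(256L, ceiling((n - nrow(pts)) * 9))
    if (is.null(axis)) {
      u <- matrix(rnorm(3 * draw), draw, 3L)
      u <- u / sqrt(rowSums(u^2))
    } else {
      z <- runif(draw, cos(theta_max), 1)
      phi <- runif(draw, 0, 2 * pi)
      s <- sqrt(pmax(0, 1 - z^2))
      u <- cbind(s * cos(phi), s * sin(phi), z) %*% basis
    }
    r <- .phantom_radius(u)
    keep <- runif(draw) < (r / r_cap)^2
    pts <- rbind(pts, u[keep, , drop = FALSE] * r[keep])
    nrm <- rbind(nrm, u[keep, , drop = FALSE])
  }
  list(points = pts[seq_len(n), , drop = FALSE],
       normals = nrm[seq_len(n), , drop = FALSE])
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Generate a vertebra-like phantom surface cloud
#'
#' Samples `n_points` area-uniformly from a parametric closed surface:
#' an ellipsoidal body with a long "spinous process" protrusion and two
#' transverse processes. The protrusion tip has markedly higher
#' surface-variation curvature than the body, which is what the matcher
#' keys on. Deterministic given `seed`.
#'
#' @param seed integer RNG seed.
#' @param n_points number of surface points (>= 500).
#' @return A [point_cloud()] tagged `"synthetic"`.
#' @export
make_phantom <- function(seed, n_points = 4096L) {
  if (n_points < 500L) stop("n_points must be >= 500")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  d <- .phantom_draw(n_points)
  point_cloud(d$points, source_tag = "synthetic")
}

#' Specification of a synthetic registration pair
#'
#' Defaults mirror the study regime: overlap drawn uniformly from
#' 1.3-4.3 %, per-axis initial rotations up to 170 degrees and
#' translations up to 115 mm, intra-operative density twice the
#' pre-operative, and optional additive Gaussian noise.
#'
#' @param n_preop pre-operative cloud size.
#' @param n_intraop intra-operative cloud size; `NULL` derives it from
#'   `density_ratio`.
#' @param overlap_target overlap fraction in (0, 1]; `NULL` draws
#'   uniformly from `[0.013, 0.043]`.
#' @param rotation_range_deg per-axis rotation bound (deg).
#' @param translation_range_mm per-component translation bound (mm).
#' @param noise_sigma_mm Gaussian noise sd per coordinate (mm).
#' @param density_ratio intra-/pre-operative point density over the
#'   shared patch.
#' @param seed integer seed; every field of the pair is reproducible
#'   from it.
#' @export
pair_spec <- function(n_preop = 16384L, n_intraop = NULL,
                      overlap_target = NULL, rotation_range_deg = 170,
                      translation_range_mm = 115, noise_sigma_mm = 0,
                      density_ratio = 2, seed = 1L) {
  if (!is.null(overlap_target) &&
      (overlap_target <= 0 || overlap_target > 1)) {
    stop("overlap_target must be in (0, 1]")
  }
  if (noise_sigma_mm < 0) stop("noise_sigma_mm must be >= 0")
  structure(list(n_preop = as.integer(n_preop),
                 n_intraop = if (!is.null(n_intraop)) as.integer(n_intraop),
                 overlap_target = overlap_target,
                 rotation_range_deg = rotation_range_deg,
                 translation_range_mm = translation_range_mm,
                 noise_sigma_mm = noise_sigma_mm,
                 density_ratio = density_ratio,
                 seed = as.integer(seed)),
            class = "pair_spec")
}

#' Overlap ratio between two clouds under a known alignment
#'
#' Fraction of `preop` points that have a `T_G`-transformed `intraop`
#' point within `tau` mm. `tau` defaults to twice the pre-operative
#' cloud's median nearest-neighbor spacing.
#'
#' @param preop,intraop [point_cloud()]s.
#' @param T_G `rigid_transform` mapping intraop into the preop frame.
#' @param tau coverage radius in mm.
#' @export
overlap_ratio <- function(preop, intraop, T_G, tau = NULL) {
  if (is.null(tau)) tau <- 2 * median_nn_spacing(preop)
  if (tau <= 0) stop("tau must be > 0")
  moved <- apply_transform(intraop, T_G)
  nn <- knn_cpp(preop$points, moved$points, 1L, FALSE)
  mean(nn$dist[, 1L] <= tau)
}

#' Generate a synthetic cross-source registration pair with ground truth
#'
#' Builds a full phantom as the pre-operative cloud, then independently
#' re-samples the surface over a small patch anchored near the spinous
#' process tip (front-facing points only, emulating a scanner's limited
#' exposure), at `density_ratio` times the pre-operative density. The
#' patch radius is calibrated so the tau-ball overlap ratio hits
#' `overlap_target`. The patch is then moved by a random rigid pose
#' drawn within the configured ranges and perturbed with isotropic
#' Gaussian noise. The stored ground truth maps the intra-operative
#' cloud back into the pre-operative frame (exactly, pre-noise).
#'
#' @param spec a [pair_spec()].
#' @return A `synthetic_pair`: list with `preop`, `intraop`,
#'   `ground_truth` (mapping intraop into the preop frame),
#'   `achieved_overlap`, the drawn `pose_angles_deg` /
#'   `pose_translation_mm`, and `spec`. When `density_ratio` is exactly
#'   1 (and `n_intraop` unset) the patch is an exact subset of the
#'   pre-operative samples; otherwise it is an independent re-sampling
#'   of the surface.
#' @export
make_pair <- function(spec = pair_spec()) {
  stopifnot(inherits(spec, "pair_spec"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(spec$seed)
  pre <- .phantom_draw(spec$n_preop)
  preop <- point_cloud(pre$points, source_tag = "preop")
  target <- spec$overlap_target
  if (is.null(target)) target <- runif(1, 0.013, 0.043)
  # anchor near the spinous process tip, jittered along the protrusion
  tip <- .phantom_tip()
  anchor <- tip + c(runif(1, -2, 2), runif(1, 0, 6), runif(1, -2, 2))
  dists <- sqrt(rowSums(sweep(pre$points, 2L, anchor)^2))
  tau <- 2 * median_nn_spacing(preop)
  view <- anchor / sqrt(sum(anchor^2))
  rho <- as.numeric(quantile(dists, min(1, target)))
  patch_local <- NULL
  achieved <- NA_real_
  if (spec$density_ratio == 1 && is.null(spec$n_intraop)) {
    # unit density ratio: the intra-operative patch is an exact subset
    # of the pre-operative samples (single-source sanity regime)
    patch_local <- pre$points[dists <= rho, , drop = FALSE]
    achieved <- overlap_ratio(preop, point_cloud(patch_local),
                              identity_transform(), tau)
  } else {
    for (attempt in 1:4) {
      n_in_patch <- sum(dists <= rho)
      n_intra <- if (!is.null(spec$n_intraop)) spec$n_intraop else {
        max(50L, as.integer(round(spec$density_ratio * n_in_patch)))
      }
      # rejection-sample fresh surface points restricted to the patch
      got <- matrix(NA_real_, 0L, 3L)
      tries <- 0L
      cap <- min(pi, rho / 15 + 0.25)  # covers the patch ball
      while (nrow(got) < n_intra && tries < 60L) {
        d <- .phantom_draw(max(200L, 4L * n_intra), axis = anchor,
                           theta_max = cap)
        dd <- sqrt(rowSums(sweep(d$points, 2L, anchor)^2))
        facing <- d$normals %*% view > 0
        keep <- dd <= rho & facing
        got <- rbind(got, d$points[keep, , drop = FALSE])
        tries <- tries + 1L
      }
      if (nrow(got) < n_intra) {
        stop(sprintf(paste0("overlap_target %.4f unreachable for this ",
                            "geometry; feasible range is roughly ",
                            "[0.005, 0.25]"), target))
      }
      patch_local <- got[seq_len(n_intra), , drop = FALSE]
      achieved <- overlap_ratio(preop, point_cloud(patch_local),
                                identity_transform(), tau)
      if (achieved >= 0.8 * target && achieved <= 1.25 * target) break
      # patch-radius recalibration: front-facing culling shrinks coverage
      rho <- rho * sqrt(target / max(achieved, 1e-6))
    }
  }
  ang <- runif(3, -spec$rotation_range_deg, spec$rotation_range_deg)
  tr <- runif(3, -spec$translation_range_mm, spec$translation_range_mm)
  pose <- rigid_transform(rot_z(ang[3]) %*% rot_y(ang[2]) %*% rot_x(ang[1]),
                          tr)
  intrap <- sweep(patch_local %*% t(pose$rotation), 2L, pose$translation, "+")
  if (spec$noise_sigma_mm > 0) {
    intrap <- intrap + matrix(rnorm(length(intrap), sd = spec$noise_sigma_mm),
                              nrow(intrap), 3L)
  }
  structure(list(preop = preop,
                 intraop = point_cloud(intrap, source_tag = "intraop"),
                 ground_truth = invert(pose),
                 achieved_overlap = achieved,
                 pose_angles_deg = ang,
                 pose_translation_mm = tr,
                 spec = spec),
            class = "synthetic_pair")
}

#' @export
print.synthetic_pair <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_pair> preop %d pts, intraop %d pts, ",
                     "overlap %.2f %%, noise %.2f mm\n"),
              n_points(x$preop), n_points(x$intraop),
              100 * x$achieved_overlap, x$spec$noise_sigma_mm))
  invisible(x)
}

#' Re-noise the intra-operative cloud of an existing pair
#'
#' Replaces the additive Gaussian perturbation of a pair's
#' intra-operative cloud with a fresh draw at standard deviation
#' `sigma`, regenerating the pair at its own seed so the underlying
#' geometry and pose are identical.
#'
#' @param pair a `synthetic_pair`.
#' @param sigma noise standard deviation in mm.
#' @param noise_seed seed for the fresh noise draw.
#' @return A `synthetic_pair`.
#' @export
renoise_pair <- function(pair, sigma, noise_seed = pair$spec$seed + 10000L) {
  stopifnot(inherits(pair, "synthetic_pair"))
  clean_spec <- pair$spec
  clean_spec$noise_sigma_mm <- 0
  clean <- make_pair(clean_spec)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(noise_seed)
  pts <- clean$intraop$points
  if (sigma > 0) pts <- pts + matrix(rnorm(length(pts), sd = sigma),
                                     nrow(pts), 3L)
  clean$intraop <- point_cloud(pts, source_tag = "intraop")
  clean$spec$noise_sigma_mm <- sigma
  clean
}
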