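#' Farthest point sampling
#'
#' Greedy max-min subsampling: starting from `seed_index`, each new
#' sample is the point maximizing the minimum distance to the already
#' selected set. Distance ties are broken by lowest index, so the result
#' is fully deterministic.
#'
#' @param cloud a [point_cloud()].
#' @param k number of samples, `1 <= k <= n`.
#' @param seed_index 1-based index of the first sample (default 1).
#' @return Integer vector of `k` distinct indices in selection order.
#' @export
farthest_point_sample <- function(cloud, k, seed_index = 1L) {
  stopifnot(inherits(cloud, "point_cloud"))
  n <- n_points(cloud)
  k <- as.integer(k)
  if (k < 1L || k > n) stop("k must be between 1 and the number of points")
  as.integer(fps_cpp(cloud$points, k, as.integer(seed_index)))
}

#' Decompose a cloud into FPS-centred local regions
#'
#' Runs farthest point sampling to pick `k` sample points, then assigns
#' to each sample every cloud point within `region_radius` of it (closed
#' ball, so each sample point belongs to its own region). Regions
#' overlap; together they form the candidate set the matcher traverses.
#'
#' @param cloud a [point_cloud()] (typically the pre-operative surface).
#' @param k number of regions (default 25).
#' @param region_radius ball radius in mm.
#' @param seed_index FPS starting index.
#' @return A `local_region_set`: list with `sample_indices`,
#'   `sample_points` (k x 3), `regions` (list of index vectors) and
#'   `region_radius`.
#' @export
extract_regions <- function(cloud, k = 25L, region_radius, seed_index = 1L) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (region_radius <= 0) stop("region_radius must be > 0")
  idx <- farthest_point_sample(cloud, k, seed_index)
  ctrs <- cloud$points[idx, , drop = FALSE]
  grp <- radius_groups_cpp(ctrs, cloud$points, region_radius, 0L)
  structure(list(sample_indices = idx,
                 sample_points = ctrs,
                 regions = lapply(grp$index, as.integer),
                 region_radius = region_radius),
            class = "local_region_set")
}

#' @export
print.local_region_set <- function(x, ...) {
  sz <- lengths(x$regions)
  cat(sprintf("<local_region_set> %d regions, radius %.2f mm, %d-%d points each\n",
              length(x$regions), x$region_radius, min(sz), max(sz)))
  invisible(x)
}

#' Down-sample a dense cloud to match a reference density
#'
#' Voxel-grid down-sampling of `dense` with the voxel edge chosen (by
#' bisection on the voxel size) so that the output's median
#' nearest-neighbor spacing lies within 20 % of the reference cloud's.
#' Used to remove the cross-source density mismatch before matching. If
#' the reference is already sparser than `dense` can be made (or has a
#' single point), `dense` is returned unchanged with a warning.
#'
#' @param dense the denser [point_cloud()] (typically intra-operative).
#' @param reference the [point_cloud()] whose density is the target.
#' @return A down-sampled [point_cloud()] (indices into `dense`, so
#'   features survive).
#' @export
equalize_density <- function(dense, reference) {
  stopifnot(inherits(dense, "point_cloud"), inherits(reference, "point_cloud"))
  if (n_points(reference) < 2L || n_points(dense) < 2L) {
    warning("degenerate cloud; returning dense cloud unchanged")
    return(dense)
  }
  target <- median_nn_spacing(reference)
  current <- median_nn_spacing(dense)
  if (current >= 0.8 * target) {
    if (current > 1.25 * target) {
      message("cloud is already sparser than the reference; returned unchanged")
    }
    return(dense)
  }
  # spacing grows monotonically with voxel size; bisect
  lo <- current
  hi <- 4 * target
  best <- NULL
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    keep <- as.integer(voxel_downsample_cpp(dense$points, mid))
    sub <- subset_cloud(dense, keep)
    sp <- if (n_points(sub) >= 2L) median_nn_spacing(sub) else Inf
    if (sp < target) lo <- mid else hi <- mid
    if (is.finite(sp) && abs(sp - target) / target <= 0.2) {
      best <- sub
      if (abs(sp - target) / target <= 0.05) break
    }
  }
  if (is.null(best)) {
    warning("could not match reference spacing within 20 %; unchanged")
    return(dense)
  }
  best
}
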