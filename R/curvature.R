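#' Curvature configuration
#'
#' Controls the surface-variation estimate: the neighborhood ball radius
#' (mm) and the minimum neighbor count below which a point is treated as
#' degenerate (flat, sigma = 0).
#'
#' @param neighborhood_radius ball radius in mm (default 5, the scale of
#'   local vertebral surface detail).
#' @param min_neighbors minimum points (including the query) for a valid
#'   covariance; at least 3.
#' @export
curvature_config <- function(neighborhood_radius = 5.0, min_neighbors = 5L) {
  if (neighborhood_radius <= 0) stop("neighborhood_radius must be > 0")
  min_neighbors <- as.integer(min_neighbors)
  if (min_neighbors < 3L) stop("min_neighbors must be >= 3")
  structure(list(neighborhood_radius = neighborhood_radius,
                 min_neighbors = min_neighbors),
            class = "curvature_config")
}

#' Surface-variation curvature per point
#'
#' For each point, takes all cloud points within `neighborhood_radius`
#' (the point itself included), forms the covariance of the neighborhood
#' about its centroid, and computes
#' `sigma = lambda_3 / (lambda_1 + lambda_2 + lambda_3)` from the
#' eigenvalues sorted descending. `sigma` is 0 on a plane, 1/3 for a
#' fully isotropic neighborhood, and invariant under rigid motion and
#' uniform scaling. Neighborhoods with fewer than `min_neighbors` points
#' get `sigma = 0`; their count is reported as an attribute
#' `n_degenerate` on the returned cloud.
#'
#' @param cloud a [point_cloud()].
#' @param cfg a [curvature_config()].
#' @return The cloud with `features` set to the curvature values.
#' @examples
#' cl <- point_cloud(cbind(runif(200), runif(200), 0))
#' cl <- compute_curvature(cl, curvature_config(0.3))
#' max(cl$features)  # planar: ~0
#' @export
compute_curvature <- function(cloud, cfg = curvature_config()) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(cfg, "curvature_config"))
  res <- curvature_cpp(cloud$points, cfg$neighborhood_radius,
                       cfg$min_neighbors)
  out <- point_cloud(cloud$points, res$sigma, cloud$source_tag)
  attr(out, "n_degenerate") <- res$n_degenerate
  out
}
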