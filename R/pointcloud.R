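#' Point cloud container
#'
#' An `n x 3` matrix of coordinates in millimetres with an optional
#' per-point scalar feature channel (the surface-variation curvature once
#' [compute_curvature()] has run) and a source tag.
#'
#' @param points numeric `n x 3` matrix (mm).
#' @param features optional numeric vector of length `n`.
#' @param source_tag one of `"preop"`, `"intraop"`, `"synthetic"`, or any
#'   short label.
#' @return A `point_cloud` object.
#' @export
point_cloud <- function(points, features = NULL, source_tag = "synthetic") {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stop("points must have 3 columns")
  if (nrow(points) < 1L) stop("point cloud must contain at least one point")
  if (any(!is.finite(points))) stop("all coordinates must be finite")
  if (!is.null(features)) {
    features <- as.numeric(features)
    if (length(features) != nrow(points)) {
      stop("features must have one entry per point")
    }
    if (any(!is.finite(features))) stop("features must be finite")
  }
  structure(list(points = points, features = features,
                 source_tag = source_tag),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points [%s]%s\n", nrow(x$points),
              x$source_tag,
              if (is.null(x$features)) "" else ", with scalar features"))
  invisible(x)
}

#' Number of points in a cloud
#' @param cloud a `point_cloud`.
#' @export
n_points <- function(cloud) nrow(cloud$points)

#' Subset a point cloud by point indices
#'
#' Keeps coordinates and features together.
#'
#' @param cloud a `point_cloud`.
#' @param idx integer indices.
#' @export
subset_cloud <- function(cloud, idx) {
  point_cloud(cloud$points[idx, , drop = FALSE],
              if (!is.null(cloud$features)) cloud$features[idx],
              cloud$source_tag)
}

#' Apply a rigid transform to a point cloud
#'
#' Maps each point to `R p + t`; the feature channel is carried through
#' unchanged (curvature is rigid-invariant).
#'
#' @param cloud a `point_cloud`.
#' @param T a `rigid_transform`.
#' @return The transformed `point_cloud`.
#' @export
apply_transform <- function(cloud, T) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(T, "rigid_transform"))
  pts <- cloud$points %*% t(T$rotation)
  pts <- sweep(pts, 2L, T$translation, "+")
  point_cloud(pts, cloud$features, cloud$source_tag)
}

#' Median nearest-neighbor spacing of a cloud (mm)
#'
#' @param cloud a `point_cloud` with at least 2 points.
#' @export
median_nn_spacing <- function(cloud) {
  stopifnot(n_points(cloud) >= 2L)
  nn <- knn_cpp(cloud$points, cloud$points, 1L, TRUE)
  median(nn$dist[, 1L])
}

#' Radius of the minimal bounding sphere about the centroid (mm)
#'
#' Cheap proxy for cloud extent: the largest distance from the centroid.
#'
#' @param cloud a `point_cloud`.
#' @export
bounding_radius <- function(cloud) {
  ctr <- colMeans(cloud$points)
  sqrt(max(rowSums(sweep(cloud$points, 2L, ctr)^2)))
}
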