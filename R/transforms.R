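#' Rigid transform in 3-D
#'
#' A rotation (3x3 orthonormal, det +1) plus a translation (mm). Acts on
#' points as `R p + t`. Inputs whose rotation fails orthonormality or has
#' negative determinant (tolerance 1e-6) are rejected rather than
#' re-orthonormalized.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric translation in mm.
#' @return An object of class `rigid_transform`.
#' @examples
#' T1 <- rigid_transform(rot_z(30), c(1, 0, 0))
#' compose(T1, invert(T1))  # identity
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || anyNA(rotation) ||
      any(!is.finite(rotation))) {
    stop("rotation must be a finite 3x3 matrix")
  }
  if (length(translation) != 3L || any(!is.finite(translation))) {
    stop("translation must be a finite length-3 vector")
  }
  err <- max(abs(crossprod(rotation) - diag(3)))
  if (err > 1e-6) {
    stop(sprintf("rotation is not orthonormal (max deviation %.3g)", err))
  }
  if (det(rotation) < 0) {
    stop("rotation has negative determinant (reflection)")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  cat("rotation:\n")
  print(round(x$rotation, 6))
  cat("translation (mm):", paste(round(x$translation, 4), collapse = " "), "\n")
  invisible(x)
}

#' Identity rigid transform
#' @export
identity_transform <- function() rigid_transform()

#' Elementary rotations (degrees)
#'
#' @param deg angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

#' @rdname rot_x
#' @export
rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

#' @rdname rot_x
#' @export
rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

#' Compose two rigid transforms
#'
#' `compose(T1, T2)` acts as T1 after T2: `(T1 o T2)(p) = T1(T2(p))`.
#'
#' @param T1,T2 `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
compose <- function(T1, T2) {
  stopifnot(inherits(T1, "rigid_transform"), inherits(T2, "rigid_transform"))
  rigid_transform(T1$rotation %*% T2$rotation,
                  as.numeric(T1$rotation %*% T2$translation) + T1$translation)
}

#' Invert a rigid transform
#'
#' @param T a `rigid_transform`.
#' @return The inverse transform: `compose(T, invert(T))` is the identity.
#' @export
invert <- function(T) {
  stopifnot(inherits(T, "rigid_transform"))
  Rt <- t(T$rotation)
  rigid_transform(Rt, as.numeric(-Rt %*% T$translation))
}

#' Convert between a rigid transform and a 4x4 homogeneous matrix
#'
#' @param T a `rigid_transform`.
#' @return `transform_matrix()`: 4x4 homogeneous matrix;
#'   `transform_from_matrix()`: a `rigid_transform`.
#' @export
transform_matrix <- function(T) {
  stopifnot(inherits(T, "rigid_transform"))
  M <- diag(4)
  M[1:3, 1:3] <- T$rotation
  M[1:3, 4] <- T$translation
  M
}

#' @rdname transform_matrix
#' @param M 4x4 homogeneous matrix with bottom row (0,0,0,1).
#' @export
transform_from_matrix <- function(M) {
  M <- as.matrix(M)
  if (!all(dim(M) == c(4L, 4L))) stop("expected a 4x4 matrix")
  if (max(abs(M[4, ] - c(0, 0, 0, 1))) > 1e-9) {
    stop("bottom row must be (0, 0, 0, 1)")
  }
  rigid_transform(M[1:3, 1:3], M[1:3, 4])
}

#' Read/write a transform as a plain-text 4x4 matrix
#'
#' @param T a `rigid_transform`.
#' @param path file path.
#' @export
write_transform <- function(T, path) {
  M <- transform_matrix(T)
  writeLines(apply(M, 1L, function(r) paste(sprintf("%.17g", r), collapse = " ")),
             path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != 4L) stop("expected 4 rows in transform file")
  M <- do.call(rbind, lapply(lines, function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  transform_from_matrix(M)
}

#' Rotation and translation error against a ground-truth transform
#'
#' Forms the residual transform `dT = T o T_G^-1` and reports the geodesic
#' rotation error `e_r = arccos((trace(dR) - 1) / 2)` in degrees (argument
#' clamped to `[-1, 1]`) and the translation error `e_t = ||dt||` in mm.
#'
#' @param T estimated `rigid_transform`.
#' @param T_G ground-truth `rigid_transform`.
#' @return A `registration_error`: list with `rotation_error_deg` and
#'   `translation_error_mm`.
#' @examples
#' registration_error(rigid_transform(rot_z(30)), identity_transform())
#' @export
registration_error <- function(T, T_G) {
  dT <- compose(T, invert(T_G))
  arg <- (sum(diag(dT$rotation)) - 1) / 2
  arg <- max(-1, min(1, arg))
  structure(list(rotation_error_deg = acos(arg) * 180 / pi,
                 translation_error_mm = sqrt(sum(dT$translation^2))),
            class = "registration_error")
}

#' @export
print.registration_error <- function(x, ...) {
  cat(sprintf("e_r = %.4f deg, e_t = %.4f mm\n",
              x$rotation_error_deg, x$translation_error_mm))
  invisible(x)
}

#' Random rigid transform with per-axis Euler angles and bounded translation
#'
#' Angles are drawn uniformly in `[-rot_range_deg, rot_range_deg]` per
#' axis (applied as Rz Ry Rx) and the translation uniformly per component
#' in `[-trans_range_mm, trans_range_mm]`. Uses the current RNG state.
#'
#' @param rot_range_deg per-axis rotation bound in degrees.
#' @param trans_range_mm per-component translation bound in mm.
#' @return A `rigid_transform`.
#' @export
random_transform <- function(rot_range_deg = 170, trans_range_mm = 115) {
  ang <- runif(3, -rot_range_deg, rot_range_deg)
  tr <- runif(3, -trans_range_mm, trans_range_mm)
  rigid_transform(rot_z(ang[3]) %*% rot_y(ang[2]) %*% rot_x(ang[1]), tr)
}
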