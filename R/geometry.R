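#' Rigid 3D transform
#'
#' A rigid-body transform parameterized by Euler angles (degrees) and a
#' translation (mm). The rotation convention is Z-Y-X intrinsic: the rotation
#' matrix is `Rz %*% Ry %*% Rx`, i.e. the body is first rotated about its Z
#' axis, then the new Y, then the new X. Points transform as
#' `p' = R %*% p + t`. The identity transform has all six parameters zero.
#'
#' @param rotation numeric length-3, rotations about X, Y, Z in degrees.
#' @param translation numeric length-3, translation in mm.
#' @return An object of class `rigid3d`.
#' @export
rigid3d <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0)) {
  rotation <- as.numeric(rotation)
  translation <- as.numeric(translation)
  stopifnot(length(rotation) == 3, length(translation) == 3,
            all(is.finite(rotation)), all(is.finite(translation)))
  structure(list(rotation = rotation, translation = translation),
            class = "rigid3d")
}

rot_x <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}
rot_y <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}
rot_z <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Rotation matrix of a rigid transform
#'
#' @param tf a [rigid3d()] transform.
#' @return 3x3 rotation matrix (Z-Y-X intrinsic composition).
#' @export
rigid_rotation_matrix <- function(tf) {
  a <- tf$rotation * pi / 180
  rot_z(a[3]) %*% rot_y(a[2]) %*% rot_x(a[1])
}

#' Apply a rigid transform to points
#'
#' @param tf a [rigid3d()] transform.
#' @param pts n x 3 matrix (or length-3 vector) of points in mm.
#' @param inverse apply the inverse transform instead.
#' @return n x 3 matrix of transformed points.
#' @export
rigid_apply <- function(tf, pts, inverse = FALSE) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  R <- rigid_rotation_matrix(tf)
  if (inverse) {
    sweep(pts, 2, tf$translation) %*% R  # (p - t) %*% R == t(R^T (p-t))^T
  } else {
    pts %*% t(R) + matrix(tf$translation, nrow(pts), 3, byrow = TRUE)
  }
}

#' 2D affine transform
#'
#' Affine map of the detector plane used by the 2D augmentation of paired
#' images: `A = R(rotation) %*% Shear(shear) %*% diag(scale)`, applied about
#' the image center, followed by a translation in mm.
#'
#' @param translation numeric length-2 (mm).
#' @param rotation scalar, degrees.
#' @param scale numeric length-2 (or scalar), unitless, must be > 0.
#' @param shear scalar, degrees; shear of the x axis toward y.
#' @return An object of class `affine2d`.
#' @export
affine2d <- function(translation = c(0, 0), rotation = 0, scale = c(1, 1),
                     shear = 0) {
  if (length(scale) == 1) scale <- rep(scale, 2)
  stopifnot(length(translation) == 2, length(scale) == 2, all(scale > 0),
            is.finite(rotation), is.finite(shear))
  structure(list(translation = as.numeric(translation),
                 rotation = as.numeric(rotation),
                 scale = as.numeric(scale),
                 shear = as.numeric(shear)),
            class = "affine2d")
}

#' @rdname affine2d
#' @param tf an `affine2d` object.
#' @return `affine2d_matrix`: the 2x2 linear part.
#' @export
affine2d_matrix <- function(tf) {
  th <- tf$rotation * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  S <- matrix(c(1, 0, tan(tf$shear * pi / 180), 1), 2, 2)
  R %*% S %*% diag(tf$scale)
}

#' @rdname affine2d
#' @param pts n x 2 matrix of points (mm, about the image center).
#' @param inverse apply the inverse map.
#' @export
affine2d_apply <- function(tf, pts, inverse = FALSE) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  A <- affine2d_matrix(tf)
  if (inverse) {
    sweep(pts, 2, tf$translation) %*% t(solve(A))
  } else {
    pts %*% t(A) + matrix(tf$translation, nrow(pts), 2, byrow = TRUE)
  }
}

#' Inverse of a 2D affine transform applied as a matrix+offset pair
#' @noRd
affine2d_inverse_fun <- function(tf) {
  A <- solve(affine2d_matrix(tf))
  t0 <- tf$translation
  function(pts) sweep(pts, 2, t0) %*% t(A)
}
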