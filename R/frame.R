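#' Anatomical coordinate frame
#'
#' Origin plus right-handed orthonormal axes defining the normalized
#' coordinate system of a wrist: Z along the radial shaft axis (pointing
#' distal), X along the styloid-to-notch reference line projected
#' perpendicular to Z, Y completing the right-handed triad.
#'
#' @param origin mm.
#' @param x_axis,y_axis,z_axis unit vectors, mutually orthogonal to 1e-6.
#' @return object of class `anatomical_frame`.
#' @export
anatomical_frame <- function(origin, x_axis, y_axis, z_axis) {
  A <- cbind(x_axis, y_axis, z_axis)
  if (max(abs(crossprod(A) - diag(3))) > 1e-6)
    stop("frame axes must be orthonormal to 1e-6")
  if (det(A) < 0) stop("frame must be right-handed")
  structure(list(origin = as.numeric(origin), x_axis = as.numeric(x_axis),
                 y_axis = as.numeric(y_axis), z_axis = as.numeric(z_axis)),
            class = "anatomical_frame")
}

#' Build the anatomical frame from landmarks
#'
#' Z is the normalized radial shaft axis (proximal to distal); the origin is
#' the articular-surface point projected onto the shaft-axis line; X is the
#' unit projection of the styloid-to-notch reference line onto the plane
#' through the origin perpendicular to Z; Y = Z x X. Fixing X on the radial
#' anatomy is what unifies the rotation of the radius about Z across
#' subjects while leaving the relative ulnar position untouched.
#'
#' @param lm a [landmark_set()].
#' @return an [anatomical_frame()].
#' @export
build_frame <- function(lm) {
  p1 <- lm$shaft_axis_points[1, ]; p2 <- lm$shaft_axis_points[2, ]
  z <- p2 - p1
  z <- z / sqrt(sum(z^2))
  ref <- lm$sigmoid_notch_point - lm$styloid_point
  x <- ref - sum(ref * z) * z
  nx <- sqrt(sum(x^2))
  if (nx < 1e-6 * sqrt(sum(ref^2)) || nx == 0)
    stop("degenerate geometry: reference line parallel to the shaft axis")
  x <- x / nx
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])  # z cross x
  a <- lm$articular_surface_point
  origin <- p1 + sum((a - p1) * z) * z
  anatomical_frame(origin, x, y, z)
}

#' Canonical normalized grid
#'
#' The grid the normalization resamples onto: axes are the anatomical
#' frame's, the Z extent spans exactly +/- `fov_halfwidth` about the frame
#' origin, X/Y span +/- `xy_halfwidth`.
#'
#' @param shape voxels per axis (length-3).
#' @param fov_halfwidth Z half-extent in mm (default 40).
#' @param xy_halfwidth X/Y half-extent in mm (default `fov_halfwidth`).
#' @return a [grid3d()] in frame coordinates.
#' @export
canonical_grid <- function(shape = c(24, 24, 24), fov_halfwidth = 40,
                           xy_halfwidth = fov_halfwidth) {
  shape <- as.integer(shape)
  sp <- c(2 * xy_halfwidth / shape[1], 2 * xy_halfwidth / shape[2],
          2 * fov_halfwidth / shape[3])
  # voxel centers span the FOV symmetrically
  grid3d(shape, sp, origin = c(-xy_halfwidth + sp[1] / 2,
                               -xy_halfwidth + sp[2] / 2,
                               -fov_halfwidth + sp[3] / 2))
}

#' Normalize a volume into the anatomical frame
#'
#' Resamples the CT (trilinear, air fill) and label (nearest-neighbour,
#' background fill) onto the canonical grid expressed in the frame's axes.
#' Voxels outside the source volume are padded with air / background, so the
#' estimated object is exactly the bone shape within +/- `fov_halfwidth` of
#' the origin.
#'
#' @param ct a [ct_volume()].
#' @param label the paired [label_volume()].
#' @param frame an [anatomical_frame()].
#' @param fov_halfwidth Z half-extent of the field of view, mm.
#' @param shape canonical grid shape.
#' @param xy_halfwidth X/Y half-extent, mm.
#' @return object of class `normalized_sample`: list(ct, label, frame,
#'   fov_halfwidth); the contained volumes live on the canonical grid (frame
#'   coordinates, identity orientation).
#' @export
normalize_volume <- function(ct, label, frame, fov_halfwidth = 40,
                             shape = c(24, 24, 24),
                             xy_halfwidth = fov_halfwidth) {
  if (!inherits(frame, "anatomical_frame"))
    stop("frame must be an anatomical_frame")
  if (!same_geometry(ct, label))
    stop("ct and label volumes have mismatched grid geometry")
  g <- canonical_grid(shape, fov_halfwidth, xy_halfwidth)
  d <- g$shape
  xs <- g$origin[1] + (seq_len(d[1]) - 1) * g$spacing[1]
  ys <- g$origin[2] + (seq_len(d[2]) - 1) * g$spacing[2]
  zs <- g$origin[3] + (seq_len(d[3]) - 1) * g$spacing[3]
  loc <- cbind(rep.int(xs, d[2] * d[3]),
               rep.int(rep(ys, each = d[1]), d[3]),
               rep(zs, each = d[1] * d[2]))
  A <- cbind(frame$x_axis, frame$y_axis, frame$z_axis)
  world <- loc %*% t(A) + matrix(frame$origin, nrow(loc), 3, byrow = TRUE)
  hu <- sample_volume(ct, world, "trilinear", fill = -1000)
  lb <- sample_volume(label, world, "nearest", fill = 0)
  out_ct <- ct_volume(array(pmax(hu, -1024), d), spacing = g$spacing,
                      origin = g$origin)
  out_lb <- label_volume(array(as.integer(lb), d), spacing = g$spacing,
                         origin = g$origin)
  structure(list(ct = out_ct, label = out_lb, frame = frame,
                 fov_halfwidth = fov_halfwidth),
            class = "normalized_sample")
}

#' Dice overlap of a label class between two label volumes
#'
#' @param a,b `label_volume`s on the same grid.
#' @param class_id class to compare.
#' @return Dice coefficient in \[0, 1\].
#' @export
label_dice <- function(a, b, class_id = 1) {
  stopifnot(all(dim(a$voxels) == dim(b$voxels)))
  va <- a$voxels == class_id
  vb <- b$voxels == class_id
  denom <- sum(va) + sum(vb)
  if (denom == 0) return(NA_real_)
  2 * sum(va & vb) / denom
}
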