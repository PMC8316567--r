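#' Regular 3D grid geometry
#'
#' @param shape integer length-3, number of voxels per axis.
#' @param spacing numeric, voxel size in mm (scalar or length-3).
#' @param origin world coordinates (mm) of the center of voxel (1,1,1);
#'   default centers the grid on the world origin.
#' @return object of class `grid3d`.
#' @export
grid3d <- function(shape, spacing = 1, origin = NULL) {
  shape <- as.integer(shape)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  stopifnot(length(shape) == 3, all(shape >= 2), all(spacing > 0))
  if (is.null(origin)) origin <- -(shape - 1) * spacing / 2
  stopifnot(length(origin) == 3, all(is.finite(origin)))
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "grid3d")
}

check_orientation <- function(orientation) {
  stopifnot(is.matrix(orientation), all(dim(orientation) == c(3, 3)))
  if (max(abs(crossprod(orientation) - diag(3))) > 1e-6)
    stop("orientation matrix is not orthonormal")
  if (det(orientation) < 0)
    stop("orientation matrix must have determinant +1")
  invisible(orientation)
}

#' CT-like volume in Hounsfield units
#'
#' The attenuation substrate: a 3D scalar grid of Hounsfield units (HU) with
#' voxel spacing, world origin (center of the first voxel) and an orthonormal
#' direction matrix whose columns are the world directions of the grid axes.
#'
#' @param voxels 3D numeric array, HU in \[-1024, 3000\].
#' @param spacing voxel size in mm (scalar or length-3), > 0.
#' @param origin world position (mm) of the center of voxel (1,1,1).
#' @param orientation 3x3 orthonormal direction matrix, det +1.
#' @return object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing = 1, origin = NULL,
                      orientation = diag(3)) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3)
  if (any(!is.finite(voxels))) stop("non-finite HU values in volume")
  rng <- range(voxels)
  if (rng[1] < -1024 || rng[2] > 3000)
    stop(sprintf("HU outside [-1024, 3000]: range %.1f..%.1f", rng[1], rng[2]))
  g <- grid3d(dim(voxels), spacing, origin)
  check_orientation(orientation)
  structure(list(voxels = voxels, spacing = g$spacing, origin = g$origin,
                 orientation = orientation),
            class = "ct_volume")
}

#' Per-voxel bone label volume
#'
#' Classes: 0 background, 1 radius, 2 ulna. Shares its grid geometry with a
#' paired [ct_volume()].
#'
#' @param voxels 3D array of class ids in \{0, 1, 2\}.
#' @inheritParams ct_volume
#' @return object of class `label_volume`.
#' @export
label_volume <- function(voxels, spacing = 1, origin = NULL,
                         orientation = diag(3)) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3)
  if (!all(voxels %in% c(0, 1, 2)))
    stop("label classes must be in {0, 1, 2}")
  g <- grid3d(dim(voxels), spacing, origin)
  check_orientation(orientation)
  structure(list(voxels = voxels, spacing = g$spacing, origin = g$origin,
                 orientation = orientation),
            class = "label_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s @ %s mm, HU %.0f..%.0f\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  tab <- table(factor(x$voxels, levels = 0:2))
  cat(sprintf("<label_volume> %s @ %s mm, bg/radius/ulna = %s\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              paste(tab, collapse = "/")))
  invisible(x)
}

same_geometry <- function(a, b, tol = 1e-6) {
  all(dim(a$voxels) == dim(b$voxels)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol &&
    max(abs(a$orientation - b$orientation)) < tol
}

#' World coordinates of every voxel center
#' @param vol a `ct_volume` / `label_volume`.
#' @return n x 3 matrix, rows in array order (x fastest).
#' @export
voxel_centers <- function(vol) {
  d <- dim(vol$voxels)
  idx <- cbind(
    rep.int(seq_len(d[1]) - 1L, d[2] * d[3]),
    rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3]),
    rep(seq_len(d[3]) - 1L, each = d[1] * d[2])
  )
  index_to_world(vol, idx)
}

index_to_world <- function(vol, idx0) {
  pts <- sweep(idx0, 2, vol$spacing, `*`) %*% t(vol$orientation)
  sweep(pts, 2, vol$origin, `+`)
}

world_to_index <- function(vol, pts) {
  rel <- sweep(pts, 2, vol$origin) %*% vol$orientation
  sweep(rel, 2, vol$spacing, `/`)
}

#' Sample a volume at world points
#'
#' @param vol a `ct_volume` or `label_volume`.
#' @param pts n x 3 matrix of world coordinates (mm).
#' @param method "trilinear" or "nearest".
#' @param fill value for points outside the grid.
#' @return numeric vector of sampled values.
#' @export
sample_volume <- function(vol, pts,
                          method = c("trilinear", "nearest"),
                          fill = 0) {
  method <- match.arg(method)
  idx <- world_to_index(vol, pts)
  v <- as.double(vol$voxels)
  if (method == "trilinear") {
    .trilinear_cpp(v, dim(vol$voxels), idx, fill)
  } else {
    .nearest_cpp(v, dim(vol$voxels), idx, fill)
  }
}

#' Write / read volumes as NIfTI
#'
#' Thin wrappers over RNifti keeping spacing; the world origin is stored in
#' the qform offset.
#'
#' @param vol a `ct_volume` or `label_volume`.
#' @param path output `.nii` / `.nii.gz` path.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$voxels)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @param label read as a `label_volume` instead of a `ct_volume`.
#' @export
read_volume <- function(path, label = FALSE) {
  img <- RNifti::readNifti(path)
  vox <- array(as.numeric(img), dim = dim(img))
  sp <- RNifti::pixdim(img)[seq_len(3)]
  if (label) label_volume(round(vox), spacing = sp)
  else ct_volume(vox, spacing = sp)
}
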