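#' DRR image container
#'
#' A digitally reconstructed radiograph: a 2D grid of line-integrated linear
#' attenuation (dimensionless optical depth). Pixel \[i, j\] lies at detector
#' coordinates `(i - (nu+1)/2) * spacing` along the detector u axis and
#' likewise for j along v.
#'
#' @param pixels 2D numeric matrix.
#' @param spacing pixel size in mm (scalar or length-2).
#' @param geometry optional [projection_geometry()] the image was rendered
#'   with.
#' @return object of class `drr_image`.
#' @export
drr_image <- function(pixels, spacing = 1, geometry = NULL) {
  stopifnot(is.matrix(pixels))
  if (any(!is.finite(pixels))) stop("non-finite pixels in DRR image")
  if (length(spacing) == 1) spacing <- rep(spacing, 2)
  stopifnot(all(spacing > 0))
  structure(list(pixels = pixels, spacing = as.numeric(spacing),
                 geometry = geometry),
            class = "drr_image")
}

#' @export
print.drr_image <- function(x, ...) {
  cat(sprintf("<drr_image> %dx%d @ %s mm, range %.4f..%.4f\n",
              nrow(x$pixels), ncol(x$pixels),
              paste(signif(x$spacing, 3), collapse = "x"),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Attenuation model
#'
#' Maps Hounsfield units to a linear attenuation coefficient (1/mm):
#' `mu = global_scale * max(0, mu_water * (1 + HU/1000))`, so water maps to
#' `global_scale * mu_water` and air (-1000 HU) to zero. `mu_water` defaults
#' to 0.02/mm (water around 60-70 keV). `global_scale` is a dimensionless
#' calibration factor; the default is calibrated so the reference wrist
#' phantom's segmented-bone DRR peaks near 0.20 optical depth, the upper end
#' of the display range the downstream networks are trained on.
#'
#' @param mu_water attenuation of water in 1/mm, > 0.
#' @param global_scale unitless calibration factor, > 0.
#' @return object of class `attenuation_model`.
#' @export
attenuation_model <- function(mu_water = 0.02, global_scale = 0.285) {
  stopifnot(mu_water > 0, global_scale > 0)
  structure(list(mu_water = mu_water, global_scale = global_scale),
            class = "attenuation_model")
}

#' Convert HU to linear attenuation
#'
#' @param ct a [ct_volume()].
#' @param model an [attenuation_model()].
#' @return a `ct_volume`-shaped list whose `voxels` hold mu in 1/mm.
#' @export
hu_to_mu <- function(ct, model = attenuation_model()) {
  if (any(!is.finite(ct$voxels))) stop("non-finite HU values")
  mu <- model$global_scale * pmax(model$mu_water * (1 + ct$voxels / 1000), 0)
  out <- ct
  out$voxels <- mu
  class(out) <- "mu_volume"
  out
}

#' Projection geometry
#'
#' Defines the detector and ray bundle of a DRR rendering. The default is an
#' orthographic projection along -Y (a posteroanterior analog for a volume
#' whose bone axis runs along Z): rays travel in direction `view_direction`,
#' the detector u axis is the projection-orthogonal horizontal and v the
#' vertical. A perspective (pinhole) mode with a configurable source distance
#' is available; the analytic test oracles are exact under orthography.
#'
#' @param mode "orthographic" or "perspective".
#' @param view_direction unit vector of ray travel (world mm).
#' @param size detector size in pixels, length-2 (u, v).
#' @param spacing detector pixel spacing in mm, scalar or length-2.
#' @param center world position (mm) the detector is centered on.
#' @param source_distance source-to-center distance in mm (perspective only).
#' @param step_length ray-marching step in mm; must not exceed the smallest
#'   voxel spacing of the rendered volume.
#' @return object of class `projection_geometry`.
#' @export
projection_geometry <- function(mode = c("orthographic", "perspective"),
                                view_direction = c(0, -1, 0),
                                size = c(64, 64), spacing = 1,
                                center = c(0, 0, 0),
                                source_distance = 1000,
                                step_length = 0.5) {
  mode <- match.arg(mode)
  view_direction <- as.numeric(view_direction)
  nv <- sqrt(sum(view_direction^2))
  if (abs(nv - 1) > 1e-6) stop("view_direction must be unit-norm")
  if (length(spacing) == 1) spacing <- rep(spacing, 2)
  stopifnot(length(size) == 2, all(size >= 1), all(spacing > 0),
            step_length > 0, source_distance > 0)
  structure(list(mode = mode, view_direction = view_direction,
                 size = as.integer(size), spacing = as.numeric(spacing),
                 center = as.numeric(center),
                 source_distance = source_distance,
                 step_length = step_length),
            class = "projection_geometry")
}

# Orthonormal detector basis (u, v) perpendicular to the viewing direction.
detector_basis <- function(d) {
  up <- if (abs(d[3]) > 0.9) c(1, 0, 0) else c(0, 0, 1)
  u <- c(up[2] * d[3] - up[3] * d[2],
         up[3] * d[1] - up[1] * d[3],
         up[1] * d[2] - up[2] * d[1])  # up x d
  u <- u / sqrt(sum(u^2))
  v <- c(d[2] * u[3] - d[3] * u[2],
         d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])    # d x u
  list(u = u, v = v)
}

#' Render a DRR by ray integration
#'
#' Fixed-step ray marching with trilinear sampling: every detector pixel
#' accumulates `sum(mu(sample) * step_length)` along its ray. Rays that miss
#' the volume yield 0. An optional rigid `pose` renders the volume as if
#' transformed by it (the rays are traced through the inversely transformed
#' volume, which is exact for rigid motion).
#'
#' @param mu attenuation volume from [hu_to_mu()].
#' @param geom a [projection_geometry()].
#' @param pose optional [rigid3d()] pose of the volume.
#' @return a [drr_image()].
#' @export
render_drr <- function(mu, geom, pose = NULL) {
  if (geom$step_length > min(mu$spacing) + 1e-12)
    stop(sprintf(
      "step_length %.3f mm exceeds the smallest voxel spacing %.3f mm; refusing imprecise integration",
      geom$step_length, min(mu$spacing)))
  d <- geom$view_direction
  uv <- detector_basis(d)
  nu <- geom$size[1]; nvp <- geom$size[2]
  us <- (seq_len(nu) - (nu + 1) / 2) * geom$spacing[1]
  vs <- (seq_len(nvp) - (nvp + 1) / 2) * geom$spacing[2]
  # ray length: cover the volume's bounding sphere about its center
  dims <- dim(mu$voxels)
  half <- (dims - 1) * mu$spacing / 2
  vol_center <- mu$origin + mu$orientation %*% half
  R <- sqrt(sum(half^2)) + 2 * max(mu$spacing)
  nsteps <- ceiling(2 * R / geom$step_length)
  # detector pixel centers in world coordinates
  pu <- rep(us, times = nvp)
  pv <- rep(vs, each = nu)
  pix <- cbind(geom$center[1] + pu * uv$u[1] + pv * uv$v[1],
               geom$center[2] + pu * uv$u[2] + pv * uv$v[2],
               geom$center[3] + pu * uv$u[3] + pv * uv$v[3])
  if (geom$mode == "orthographic") {
    # start each ray upstream of the volume, march along d
    back <- as.numeric(d %*% (geom$center - vol_center))
    orig <- pix - matrix(d * (R + back), nrow(pix), 3, byrow = TRUE)
    dirs <- matrix(d, nrow(pix), 3, byrow = TRUE)
  } else {
    src <- geom$center - d * geom$source_distance
    dirs <- pix - matrix(src, nrow(pix), 3, byrow = TRUE)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    # march from the source; extend across the volume
    nsteps <- ceiling((geom$source_distance + 2 * R) / geom$step_length)
    orig <- matrix(src, nrow(pix), 3, byrow = TRUE)
  }
  if (!is.null(pose)) {
    Rm <- rigid_rotation_matrix(pose)
    orig <- sweep(orig, 2, pose$translation) %*% Rm
    dirs <- dirs %*% Rm
  }
  if (geom$mode == "perspective" && !is.null(pose)) {
    vals <- ray_march_perray(mu, orig, dirs, nsteps, geom$step_length)
  } else if (geom$mode == "perspective") {
    vals <- ray_march_perray(mu, orig, dirs, nsteps, geom$step_length)
  } else {
    # shared direction: single C++ call
    idx0 <- world_to_index(mu, orig)
    dir1 <- (dirs[1, ] %*% mu$orientation) / mu$spacing * geom$step_length
    vals <- .ray_march_cpp(as.double(mu$voxels), dim(mu$voxels), idx0,
                           as.double(dir1), as.integer(nsteps),
                           geom$step_length)
  }
  drr_image(matrix(vals, nu, nvp), spacing = geom$spacing, geometry = geom)
}

# perspective rays have per-pixel directions; march in chunks through the
# trilinear sampler
ray_march_perray <- function(mu, orig, dirs, nsteps, step) {
  v <- as.double(mu$voxels)
  dm <- dim(mu$voxels)
  acc <- numeric(nrow(orig))
  idx <- world_to_index(mu, orig)
  didx <- (dirs %*% mu$orientation) / matrix(mu$spacing, nrow(dirs), 3,
                                             byrow = TRUE) * step
  for (s in seq_len(nsteps)) {
    acc <- acc + .trilinear_cpp(v, dm, idx, 0)
    idx <- idx + didx
  }
  acc * step
}

#' Render a segmented-bone DRR
#'
#' Identical to [render_drr()] after zeroing attenuation outside the bone
#' label classes (radius, ulna): the DRR of the bone-only volume, which
#' suppresses soft-tissue background.
#'
#' @param ct a [ct_volume()].
#' @param label the paired [label_volume()].
#' @param geom a [projection_geometry()].
#' @param model an [attenuation_model()].
#' @param pose optional [rigid3d()] pose.
#' @param classes label classes kept (default bone classes 1 and 2).
#' @return a [drr_image()].
#' @export
render_bone_drr <- function(ct, label, geom, model = attenuation_model(),
                            pose = NULL, classes = c(1, 2)) {
  if (!same_geometry(ct, label))
    stop("ct and label volumes have mismatched grid geometry")
  mu <- hu_to_mu(ct, model)
  mu$voxels[!(label$voxels %in% classes)] <- 0
  render_drr(mu, geom, pose = pose)
}

#' Calibrate the attenuation scale on a reference phantom
#'
#' Adjusts `global_scale` so the segmented-bone DRR of the given phantom
#' peaks at `target_peak` optical depth.
#'
#' @param ct,label,geom as in [render_bone_drr()].
#' @param model starting model.
#' @param target_peak desired maximum bone-DRR intensity.
#' @return an [attenuation_model()] with adjusted `global_scale`.
#' @export
calibrate_attenuation <- function(ct, label, geom,
                                  model = attenuation_model(),
                                  target_peak = 0.20) {
  img <- render_bone_drr(ct, label, geom, model)
  peak <- max(img$pixels)
  if (peak <= 0) stop("reference phantom produced an empty bone DRR")
  attenuation_model(mu_water = model$mu_water,
                    global_scale = model$global_scale * target_peak / peak)
}
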