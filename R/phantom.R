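#' Phantom specification
#'
#' Parameters of one synthetic wrist phantom: two elongated bones (a
#' radius-like tapered cylinder with a styloid cap and an ulna-like cylinder
#' with a bulbed head) inside an elliptic soft-tissue envelope. All lengths
#' are in mm. Canonical pose: the radius shaft runs along +Z with its distal
#' articular face at z = 0; the ulna sits at an azimuth given by
#' `ulna_axial_rotation` (forearm-rotation variability).
#'
#' @param seed integer identity of the draw.
#' @param radius_params list: `length`, `r_distal`, `taper` (proximal radius
#'   = `taper * r_distal`, in (0, 1\]), `styloid_amp` (height of the distal
#'   styloid cap).
#' @param ulna_params list: `length`, `r_shaft`, `head_r` (head cap radius,
#'   at least `r_shaft`), `head_amp` (head cap height).
#' @param inter_bone_gap minimal surface-to-surface clearance, > 0.
#' @param ulna_axial_rotation azimuth of the ulna about the radius axis, deg.
#' @param soft_tissue_radii length-2 semi-axes of the soft-tissue envelope.
#' @param cortical_thickness cortical shell thickness, mm.
#' @param hu_levels named numeric: `air < soft < trabecular < cortical`.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(seed = 0L,
                         radius_params = list(length = 55, r_distal = 10,
                                              taper = 0.8, styloid_amp = 5),
                         ulna_params = list(length = 52, r_shaft = 6,
                                            head_r = 8, head_amp = 4),
                         inter_bone_gap = 3,
                         ulna_axial_rotation = 0,
                         soft_tissue_radii = c(34, 28),
                         cortical_thickness = 2,
                         hu_levels = c(air = -1000, soft = 40,
                                       trabecular = 300, cortical = 1200)) {
  lens <- c(unlist(radius_params), unlist(ulna_params),
            soft_tissue_radii, cortical_thickness)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all phantom lengths and radii must be strictly positive")
  if (inter_bone_gap <= 0) stop("inter_bone_gap must be > 0")
  if (radius_params$taper > 1)
    stop("radius taper must be <= 1 (distal end is the widest)")
  if (ulna_params$head_r < ulna_params$r_shaft)
    stop("ulna head_r must be >= r_shaft")
  if (is.unsorted(hu_levels[c("air", "soft", "trabecular", "cortical")],
                  strictly = TRUE))
    stop("hu_levels must be ordered air < soft < trabecular < cortical")
  structure(list(seed = as.integer(seed), radius_params = radius_params,
                 ulna_params = ulna_params, inter_bone_gap = inter_bone_gap,
                 ulna_axial_rotation = ulna_axial_rotation,
                 soft_tissue_radii = as.numeric(soft_tissue_radii),
                 cortical_thickness = cortical_thickness,
                 hu_levels = hu_levels),
            class = "phantom_spec")
}

#' Default phantom population
#'
#' Uniform ranges the phantom sampler draws from; loosely sized after adult
#' distal forearm anatomy (radius shaft 50-60 mm within the modeled window,
#' distal radius half-width about 1 cm, ulna slightly thinner with a bulbed
#' head, a few mm of radioulnar clearance, and up to +/-20 deg of residual
#' forearm rotation).
#'
#' @return named list of `c(lo, hi)` ranges.
#' @export
phantom_population <- function() {
  list(radius_length = c(50, 60), radius_r_distal = c(8.5, 11),
       radius_taper = c(0.7, 0.9), styloid_amp = c(4, 7),
       ulna_length = c(48, 58), ulna_r_shaft = c(5, 7),
       ulna_head_r = c(7, 9), ulna_head_amp = c(3, 5),
       inter_bone_gap = c(2, 4), ulna_axial_rotation = c(-20, 20),
       soft_a = c(30, 38), soft_b = c(24, 30),
       cortical_thickness = c(1.5, 2.5))
}

#' Draw a phantom specification from a population
#'
#' Uniform draws from the `c(lo, hi)` ranges in `population`; bitwise
#' deterministic in `seed`.
#'
#' @param seed integer >= 0.
#' @param population as [phantom_population()].
#' @return a [phantom_spec()].
#' @export
sample_phantom_spec <- function(seed, population = phantom_population()) {
  stopifnot(seed >= 0)
  for (nm in names(population)) {
    r <- population[[nm]]
    if (length(r) != 2 || r[1] > r[2])
      stop(sprintf("population range '%s' has inverted bounds", nm))
  }
  draw <- with_seed(seed, {
    vapply(population, function(r) stats::runif(1, r[1], r[2]), numeric(1))
  })
  phantom_spec(
    seed = seed,
    radius_params = list(length = draw[["radius_length"]],
                         r_distal = draw[["radius_r_distal"]],
                         taper = draw[["radius_taper"]],
                         styloid_amp = draw[["styloid_amp"]]),
    ulna_params = list(length = draw[["ulna_length"]],
                       r_shaft = draw[["ulna_r_shaft"]],
                       head_r = max(draw[["ulna_head_r"]],
                                    draw[["ulna_r_shaft"]]),
                       head_amp = draw[["ulna_head_amp"]]),
    inter_bone_gap = draw[["inter_bone_gap"]],
    ulna_axial_rotation = draw[["ulna_axial_rotation"]],
    soft_tissue_radii = c(draw[["soft_a"]], draw[["soft_b"]]),
    cortical_thickness = draw[["cortical_thickness"]])
}

#' Anatomical landmark set
#'
#' @param styloid_point tip of the radial styloid cap (mm).
#' @param sigmoid_notch_point point on the distal radius surface facing the
#'   ulna at zero forearm rotation (role analog of the volar sigmoid notch).
#' @param shaft_axis_points 2 x 3 matrix: proximal and distal points on the
#'   radial shaft axis (distinct; distal minus proximal defines +Z).
#' @param articular_surface_point center of the distal articular face.
#' @return object of class `landmark_set`.
#' @export
landmark_set <- function(styloid_point, sigmoid_notch_point,
                         shaft_axis_points, articular_surface_point) {
  pts <- rbind(styloid_point, sigmoid_notch_point, shaft_axis_points,
               articular_surface_point)
  if (any(!is.finite(pts))) stop("landmarks must be finite")
  if (sqrt(sum((shaft_axis_points[1, ] - shaft_axis_points[2, ])^2)) < 1e-9)
    stop("shaft axis points must be distinct")
  structure(list(styloid_point = as.numeric(styloid_point),
                 sigmoid_notch_point = as.numeric(sigmoid_notch_point),
                 shaft_axis_points = shaft_axis_points,
                 articular_surface_point = as.numeric(articular_surface_point)),
            class = "landmark_set")
}

# bone axis xy positions in canonical spec coordinates
phantom_axes <- function(spec) {
  rp <- spec$radius_params; up <- spec$ulna_params
  dx <- rp$r_distal + up$head_r + spec$inter_bone_gap
  phi <- spec$ulna_axial_rotation * pi / 180
  radius_xy <- c(-dx / 2, 0)
  ulna_xy <- radius_xy + dx * c(cos(phi), sin(phi))
  list(radius = radius_xy, ulna = ulna_xy, dx = dx)
}

#' Default rasterization grid for phantoms
#'
#' 96^3 voxels at 1.0 mm by default (a desk-scale grid; pass
#' `shape = rep(400, 3), spacing = 0.625` for a clinical-resolution grid).
#' The grid is centered on x/y and shifted along z so roughly 70% of the
#' extent lies proximal to the articular surface at z = 0.
#'
#' @param shape,spacing as in [grid3d()].
#' @return a `grid3d`.
#' @export
phantom_grid <- function(shape = c(96, 96, 96), spacing = 1) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  ext <- (shape - 1) * spacing
  grid3d(shape, spacing,
         origin = c(-ext[1] / 2, -ext[2] / 2, -0.7 * ext[3]))
}

#' Rasterize a phantom onto a voxel grid
#'
#' Voxelizes the analytic implicit surfaces (tapered capped cylinders with
#' half-ellipsoid cap terms) of the phantom: cortical HU within
#' `cortical_thickness` of the bone surface, trabecular HU inside, soft
#' tissue in the envelope, air elsewhere. Labels mark radius (1) and ulna
#' (2). Landmarks are computed analytically from the spec. An optional rigid
#' `pose` rasterizes the phantom rigidly moved in world space (evaluated
#' analytically, no resampling), with landmarks transformed accordingly.
#'
#' @param spec a [phantom_spec()].
#' @param grid a [grid3d()]; default [phantom_grid()].
#' @param pose optional [rigid3d()] applied to the phantom.
#' @return list with elements `ct` ([ct_volume()]), `label`
#'   ([label_volume()]), `landmarks` ([landmark_set()]).
#' @export
rasterize_phantom <- function(spec, grid = phantom_grid(), pose = NULL) {
  ax <- phantom_axes(spec)
  rp <- spec$radius_params; up <- spec$ulna_params
  # bounds check in canonical coordinates (pose may move the phantom; the
  # caller is responsible for posed phantoms staying inside the grid)
  lo <- grid$origin
  hi <- grid$origin + (grid$shape - 1) * grid$spacing
  zmin <- -max(rp$length, up$length)
  zmax <- max(rp$styloid_amp, up$head_amp)
  if (is.null(pose)) {
    ext_r <- max(abs(ax$radius)) + rp$r_distal
    ext_u <- max(abs(ax$ulna)) + up$head_r
    need <- max(ext_r, ext_u)
    if (need > min(-lo[1], hi[1], -lo[2], hi[2]) ||
        zmin < lo[3] || zmax > hi[3])
      stop(sprintf(
        "phantom extent (xy %.1f mm, z %.1f..%.1f mm) exceeds grid (x %.1f..%.1f, y %.1f..%.1f, z %.1f..%.1f)",
        need, zmin, zmax, lo[1], hi[1], lo[2], hi[2], lo[3], hi[3]))
  }
  d <- grid$shape
  xs <- grid$origin[1] + (seq_len(d[1]) - 1) * grid$spacing[1]
  ys <- grid$origin[2] + (seq_len(d[2]) - 1) * grid$spacing[2]
  zs <- grid$origin[3] + (seq_len(d[3]) - 1) * grid$spacing[3]
  pts <- cbind(rep.int(xs, d[2] * d[3]),
               rep.int(rep(ys, each = d[1]), d[3]),
               rep(zs, each = d[1] * d[2]))
  if (!is.null(pose)) pts <- rigid_apply(pose, pts, inverse = TRUE)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]

  t <- spec$cortical_thickness
  radius_in <- bone_radius_in(x, y, z, ax$radius, rp, shrink = 0)
  radius_core <- bone_radius_in(x, y, z, ax$radius, rp, shrink = t)
  ulna_in <- bone_ulna_in(x, y, z, ax$ulna, up, shrink = 0)
  ulna_core <- bone_ulna_in(x, y, z, ax$ulna, up, shrink = t)

  # soft-tissue envelope: elliptic cylinder about the midpoint of the bones,
  # long axis along the radius-ulna direction, covering the bones' z extent
  ctr <- (ax$radius + ax$ulna) / 2
  dirv <- (ax$ulna - ax$radius) / sqrt(sum((ax$ulna - ax$radius)^2))
  a <- max(spec$soft_tissue_radii[1], ax$dx / 2 + rp$r_distal + 3,
           ax$dx / 2 + up$head_r + 3)
  b <- max(spec$soft_tissue_radii[2], rp$r_distal + 3, up$head_r + 3)
  xl <- (x - ctr[1]) * dirv[1] + (y - ctr[2]) * dirv[2]
  yl <- -(x - ctr[1]) * dirv[2] + (y - ctr[2]) * dirv[1]
  soft_in <- (xl / a)^2 + (yl / b)^2 <= 1 & z >= zmin - 5 & z <= zmax + 3

  hu <- rep(spec$hu_levels[["air"]], length(x))
  hu[soft_in] <- spec$hu_levels[["soft"]]
  hu[radius_in | ulna_in] <- spec$hu_levels[["cortical"]]
  hu[radius_core | ulna_core] <- spec$hu_levels[["trabecular"]]
  lab <- integer(length(x))
  lab[radius_in] <- 1L
  lab[ulna_in] <- 2L

  ct <- ct_volume(array(hu, d), spacing = grid$spacing, origin = grid$origin)
  label <- label_volume(array(lab, d), spacing = grid$spacing,
                        origin = grid$origin)
  lm <- phantom_landmarks(spec)
  if (!is.null(pose)) {
    lm <- landmark_set(
      styloid_point = rigid_apply(pose, lm$styloid_point),
      sigmoid_notch_point = rigid_apply(pose, lm$sigmoid_notch_point),
      shaft_axis_points = rigid_apply(pose, lm$shaft_axis_points),
      articular_surface_point = rigid_apply(pose, lm$articular_surface_point))
  }
  list(ct = ct, label = label, landmarks = lm)
}

# radius-like bone: tapered cylinder z in [-L, 0] plus a styloid half-
# ellipsoid cap on the distal face, offset away from the ulna. `shrink`
# erodes the shape by approximately that margin (cortical interior).
bone_radius_in <- function(x, y, z, axis_xy, rp, shrink = 0) {
  L <- rp$length; rd <- rp$r_distal; rprox <- rp$taper * rd
  rz <- rd + (rprox - rd) * (-z / L)   # linear taper along the shaft
  rz <- pmax(rz - shrink, 0)
  shaft <- z >= -L + shrink & z <= 0 &
    (x - axis_xy[1])^2 + (y - axis_xy[2])^2 <= rz^2
  cx <- axis_xy[1] - 0.3 * rd
  ae <- max(0.6 * rd - shrink, 1e-9)
  ce <- max(rp$styloid_amp - shrink, 1e-9)
  cap <- z >= 0 & ((x - cx)^2 + (y - axis_xy[2])^2) / ae^2 + (z / ce)^2 <= 1
  shaft | cap
}

# ulna-like bone: cylinder z in [-L, -2] plus a bulbed half-ellipsoid head
# (wider than the shaft) on the distal face
bone_ulna_in <- function(x, y, z, axis_xy, up, shrink = 0) {
  ztop <- -2
  r <- max(up$r_shaft - shrink, 0)
  shaft <- z >= -up$length + shrink & z <= ztop &
    (x - axis_xy[1])^2 + (y - axis_xy[2])^2 <= r^2
  ah <- max(up$head_r - shrink, 1e-9)
  ch <- max(up$head_amp - shrink, 1e-9)
  head <- z >= ztop &
    ((x - axis_xy[1])^2 + (y - axis_xy[2])^2) / ah^2 +
      ((z - ztop) / ch)^2 <= 1
  shaft | head
}

#' Analytic landmarks of a phantom in canonical coordinates
#'
#' @param spec a [phantom_spec()].
#' @return a [landmark_set()].
#' @export
phantom_landmarks <- function(spec) {
  ax <- phantom_axes(spec)
  rp <- spec$radius_params
  rxy <- ax$radius
  landmark_set(
    styloid_point = c(rxy[1] - 0.3 * rp$r_distal, rxy[2], rp$styloid_amp),
    sigmoid_notch_point = c(rxy[1] + rp$r_distal, rxy[2], -3),
    shaft_axis_points = rbind(c(rxy, -rp$length), c(rxy, -10)),
    articular_surface_point = c(rxy, 0))
}

#' Analytic solid volumes of the phantom bones
#'
#' Closed forms: the radius is a conical frustum plus a half-ellipsoid cap,
#' `pi*L/3*(r1^2 + r1*r2 + r2^2) + (2/3)*pi*(0.6*rd)^2*amp`; the ulna is a
#' cylinder plus a half-ellipsoid head.
#'
#' @param spec a [phantom_spec()].
#' @return named numeric: `radius`, `ulna`, in mm^3.
#' @export
phantom_bone_volumes <- function(spec) {
  rp <- spec$radius_params; up <- spec$ulna_params
  rd <- rp$r_distal; rprox <- rp$taper * rd
  v_rad <- pi * rp$length / 3 * (rd^2 + rd * rprox + rprox^2) +
    2 / 3 * pi * (0.6 * rd)^2 * rp$styloid_amp
  v_uln <- pi * up$r_shaft^2 * (up$length - 2) +
    2 / 3 * pi * up$head_r^2 * up$head_amp
  c(radius = v_rad, ulna = v_uln)
}

#' Degradation parameters for simulated radiographs
#'
#' Controls the gap between a clean DRR and an "actual X-ray"-like image:
#' soft-tissue background weight, gamma nonlinearity, vignetting and seeded
#' additive Gaussian noise.
#'
#' @param soft_tissue_weight weight of the non-bone signal (1 keeps it all).
#' @param noise_sigma Gaussian noise s.d. in optical-depth units, >= 0.
#' @param gamma nonlinearity exponent, > 0.
#' @param vignette_strength quadratic radial falloff amplitude in \[0, 1).
#' @param seed integer noise seed.
#' @return object of class `degradation_params`.
#' @export
degradation_params <- function(soft_tissue_weight = 1, noise_sigma = 0.01,
                               gamma = 1.3, vignette_strength = 0.2,
                               seed = 0L) {
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (gamma <= 0) stop("gamma must be > 0")
  structure(list(soft_tissue_weight = soft_tissue_weight,
                 noise_sigma = noise_sigma, gamma = gamma,
                 vignette_strength = vignette_strength,
                 seed = as.integer(seed)),
            class = "degradation_params")
}

#' Degrade a clean DRR into an X-ray-like image
#'
#' `out = vignette(gamma_map(bone + w * (full - bone))) + noise`, where the
#' gamma map is applied on the image normalized by its maximum (so `gamma =
#' 1` is the identity), the vignette multiplies by
#' `1 - v * (r/rmax)^2` about the detector center, and the noise is seeded
#' Gaussian. With `w = 1`, `sigma = 0`, `gamma = 1`, `v = 0` the output
#' equals the input exactly. Noise may take pixels slightly negative, as in
#' a measured radiograph; rendered (noise-free) DRRs are always >= 0.
#'
#' @param clean_full_drr [drr_image()] of the full phantom (with soft
#'   tissue).
#' @param params a [degradation_params()].
#' @param bone_drr optional matching segmented-bone DRR; when given, the
#'   soft-tissue weight scales only the non-bone signal `full - bone`.
#' @return a [drr_image()].
#' @export
degrade_to_xray <- function(clean_full_drr, params, bone_drr = NULL) {
  img <- clean_full_drr$pixels
  if (any(img < 0)) stop("clean DRR must be non-negative")
  if (!is.null(bone_drr)) {
    if (!all(dim(bone_drr$pixels) == dim(img)))
      stop("bone DRR shape mismatch")
    img <- bone_drr$pixels +
      params$soft_tissue_weight * (img - bone_drr$pixels)
  } else {
    img <- params$soft_tissue_weight * img
  }
  m <- max(img)
  if (m > 0 && params$gamma != 1) img <- m * (img / m)^params$gamma
  if (params$vignette_strength != 0) {
    nu <- nrow(img); nv <- ncol(img)
    us <- (seq_len(nu) - (nu + 1) / 2)
    vs <- (seq_len(nv) - (nv + 1) / 2)
    r2 <- outer(us^2, vs^2, `+`) / max(outer(us^2, vs^2, `+`))
    img <- img * (1 - params$vignette_strength * r2)
  }
  if (params$noise_sigma > 0) {
    img <- img + with_seed(params$seed,
      matrix(stats::rnorm(length(img), 0, params$noise_sigma),
             nrow(img), ncol(img)))
  }
  drr_image(img, spacing = clean_full_drr$spacing,
            geometry = clean_full_drr$geometry)
}

#' The reference wrist phantom
#'
#' A fixed mid-population phantom used for attenuation calibration and as
#' the registration test object.
#'
#' @return a [phantom_spec()].
#' @export
reference_phantom_spec <- function() {
  phantom_spec(seed = -1L)
}
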