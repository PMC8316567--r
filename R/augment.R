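#' 3D rigid augmentation of a normalized sample
#'
#' Draws `factor` rigid transforms uniformly in the given per-axis ranges,
#' poses the normalized volume by each and renders a segmented-bone DRR of
#' the posed volume (input of the reconstruction network), paired with the
#' unposed normalized label (its target). The pose is applied to the volume
#' before projection, not as a 2D warp of the DRR.
#'
#' @param sample a `normalized_sample` from [normalize_volume()].
#' @param factor number of augmented items, >= 1.
#' @param rot_range,trans_range half-widths of the uniform ranges: degrees
#'   and mm per axis (the clinical-scale protocol uses 30 and 30).
#' @param seed integer seed; the draw is deterministic in it.
#' @param geom [projection_geometry()] for the DRRs.
#' @param model [attenuation_model()].
#' @param include_identity prepend the identity pose as the first item
#'   (factor counts it).
#' @return list of `factor` items, each `list(transform, drr, label)`.
#' @export
augment_3d <- function(sample, factor, rot_range = 30, trans_range = 30,
                       seed = 0L, geom = NULL, model = attenuation_model(),
                       include_identity = FALSE) {
  if (factor < 1) stop("augmentation factor must be >= 1")
  stopifnot(is.finite(rot_range), is.finite(trans_range))
  if (is.null(geom)) geom <- default_drr_geometry(sample)
  draws <- with_seed(seed, {
    matrix(stats::runif(factor * 6, -1, 1), factor, 6)
  })
  draws[, 1:3] <- draws[, 1:3] * rot_range
  draws[, 4:6] <- draws[, 4:6] * trans_range
  if (include_identity) draws[1, ] <- 0
  lapply(seq_len(factor), function(i) {
    tf <- rigid3d(rotation = draws[i, 1:3], translation = draws[i, 4:6])
    drr <- render_bone_drr(sample$ct, sample$label, geom, model, pose = tf)
    list(transform = tf, drr = drr, label = sample$label)
  })
}

# detector matched to the canonical FOV of a normalized sample, orthographic
# along -Y
default_drr_geometry <- function(sample, size = c(32, 32), step = NULL) {
  fovz <- sample$fov_halfwidth
  d <- dim(sample$ct$voxels)
  fovx <- d[1] * sample$ct$spacing[1] / 2
  sp <- c(2 * fovx / size[1], 2 * fovz / size[2])
  if (is.null(step)) step <- min(sample$ct$spacing)
  projection_geometry(size = size, spacing = sp, step_length = step)
}

#' 2D affine augmentation of paired images
#'
#' Expands each (X-ray-like, registration-DRR) pair `factor` times by random
#' affine transforms (translation, rotation, scaling, shear); the SAME
#' sampled transform warps both members of a pair, so pairing is preserved.
#' Warping is inverse-mapped bilinear interpolation about the image center.
#'
#' @param pairs list of `list(xray = drr_image, drr = drr_image)`; both
#'   members of a pair must share shape and spacing.
#' @param factor expansion factor, >= 1.
#' @param ranges list with `trans` (mm), `rot` (deg), `scale` (`c(lo, hi)`),
#'   `shear` (deg). Defaults keep the bones inside the frame.
#' @param seed integer seed.
#' @param include_identity make the first transform per pair the identity.
#' @return list of length `length(pairs) * factor`, items
#'   `list(xray, drr, transform, source)` with `source` the input pair
#'   index.
#' @export
augment_2d_pairs <- function(pairs, factor,
                             ranges = list(trans = 10, rot = 10,
                                           scale = c(0.9, 1.1), shear = 5),
                             seed = 0L, include_identity = FALSE) {
  if (factor < 1) stop("augmentation factor must be >= 1")
  for (p in pairs) {
    if (!all(dim(p$xray$pixels) == dim(p$drr$pixels)) ||
        max(abs(p$xray$spacing - p$drr$spacing)) > 1e-9)
      stop("xray/drr pair members must share shape and spacing")
  }
  n <- length(pairs)
  draws <- with_seed(seed, matrix(stats::runif(n * factor * 6), n * factor, 6))
  out <- vector("list", n * factor)
  k <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(factor)) {
      k <- k + 1
      dr <- draws[k, ]
      tf <- affine2d(
        translation = (2 * dr[1:2] - 1) * ranges$trans,
        rotation = (2 * dr[3] - 1) * ranges$rot,
        scale = ranges$scale[1] + dr[4:5] * diff(ranges$scale),
        shear = (2 * dr[6] - 1) * ranges$shear)
      if (include_identity && j == 1) tf <- affine2d()
      out[[k]] <- list(xray = warp_image(pairs[[i]]$xray, tf),
                       drr = warp_image(pairs[[i]]$drr, tf),
                       transform = tf, source = i)
    }
  }
  out
}

#' Warp a 2D image by an affine transform
#'
#' Inverse-mapped bilinear resampling about the image center; pixels mapping
#' outside the source are 0.
#'
#' @param img a [drr_image()] (or bare matrix, unit spacing).
#' @param tf an [affine2d()].
#' @param inverse apply the inverse transform.
#' @return a [drr_image()].
#' @export
warp_image <- function(img, tf, inverse = FALSE) {
  if (is.matrix(img)) img <- drr_image(img)
  px <- img$pixels
  nu <- nrow(px); nv <- ncol(px)
  us <- (seq_len(nu) - (nu + 1) / 2) * img$spacing[1]
  vs <- (seq_len(nv) - (nv + 1) / 2) * img$spacing[2]
  tgt <- cbind(rep.int(us, nv), rep(vs, each = nu))
  src <- affine2d_apply(tf, tgt, inverse = !inverse)
  xi <- src[, 1] / img$spacing[1] + (nu + 1) / 2 - 1
  yi <- src[, 2] / img$spacing[2] + (nv + 1) / 2 - 1
  vals <- .bilinear_cpp(px, xi, yi, 0)
  drr_image(matrix(vals, nu, nv), spacing = img$spacing,
            geometry = img$geometry)
}

#' Patient-level cross-validation split
#'
#' Assigns patients to `folds` disjoint, exhaustive test folds and, within
#' each fold's training patients, holds out about `val_frac` of the
#' *patients* for validation. Every augmented item derived from one patient
#' therefore lands entirely on one side of the train/validation divide (no
#' patient-level leakage).
#'
#' @param patient_ids vector of unique patient identifiers.
#' @param folds number of folds (default 4).
#' @param val_frac fraction of training patients held out for validation.
#' @param seed integer seed.
#' @return object of class `split_plan`: list with `fold` (integer vector
#'   named by patient: test-fold assignment) and `plan` — per fold, lists
#'   `train`, `validation`, `test` of patient ids.
#' @export
make_split <- function(patient_ids, folds = 4, val_frac = 0.15, seed = 0L) {
  patient_ids <- as.character(patient_ids)
  if (anyDuplicated(patient_ids)) stop("patient ids must be unique")
  n <- length(patient_ids)
  if (n < folds) stop("fewer patients than folds")
  perm <- with_seed(seed, sample.int(n))
  fold <- rep(seq_len(folds), length.out = n)[order(perm)]
  names(fold) <- patient_ids
  plan <- lapply(seq_len(folds), function(f) {
    test <- patient_ids[fold == f]
    rest <- patient_ids[fold != f]
    nval <- max(1, round(val_frac * length(rest)))
    val <- rest[seq_len(nval)]
    list(train = setdiff(rest, val), validation = val, test = test)
  })
  structure(list(fold = fold, plan = plan, folds = folds,
                 val_frac = val_frac, seed = as.integer(seed)),
            class = "split_plan")
}
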