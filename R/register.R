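#' Gradient correlation between two images
#'
#' The mean of the Pearson correlations of the horizontal and of the
#' vertical central-difference gradient images. Invariant to affine
#' intensity rescaling of either image; in \[-1, 1\]. Constant images (zero
#' gradient variance) raise an error rather than returning 0 — a silent zero
#' would poison the registration optimizer.
#'
#' @param a,b [drr_image()]s (or matrices) of identical shape.
#' @return scalar similarity.
#' @export
gradient_correlation <- function(a, b) {
  pa <- if (is.matrix(a)) a else a$pixels
  pb <- if (is.matrix(b)) b else b$pixels
  if (!all(dim(pa) == dim(pb))) stop("images must share shape")
  gx <- function(m) m[-c(1, 2), , drop = FALSE] - m[-(nrow(m) - 1:0), , drop = FALSE]
  gy <- function(m) m[, -c(1, 2), drop = FALSE] - m[, -(ncol(m) - 1:0), drop = FALSE]
  cors <- vapply(list(list(gx(pa), gx(pb)), list(gy(pa), gy(pb))),
                 function(g) {
    va <- stats::var(as.vector(g[[1]])); vb <- stats::var(as.vector(g[[2]]))
    if (va < 1e-24 || vb < 1e-24)
      stop("degenerate input: image has (near-)zero gradient variance")
    stats::cor(as.vector(g[[1]]), as.vector(g[[2]]))
  }, numeric(1))
  mean(cors)
}

#' Registration result
#' @noRd
registration_result <- function(transform, similarity, iterations, converged) {
  structure(list(transform = transform, similarity = similarity,
                 iterations = iterations, converged = converged),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf(
    "<registration> sim %.4f after %d evals (%s)\n  rot (deg): %s\n  trans (mm): %s\n",
    x$similarity, x$iterations,
    if (x$converged) "converged" else "not converged",
    paste(signif(x$transform$rotation, 4), collapse = ", "),
    paste(signif(x$transform$translation, 4), collapse = ", ")))
  invisible(x)
}

half_image <- function(m) {
  nu <- nrow(m) %/% 2; nv <- ncol(m) %/% 2
  0.25 * (m[2 * seq_len(nu) - 1, 2 * seq_len(nv) - 1] +
          m[2 * seq_len(nu), 2 * seq_len(nv) - 1] +
          m[2 * seq_len(nu) - 1, 2 * seq_len(nv)] +
          m[2 * seq_len(nu), 2 * seq_len(nv)])
}

#' Intensity-based 2D-3D rigid registration
#'
#' Finds the rigid pose of the CT volume whose segmented-bone DRR best
#' matches a target radiograph under the gradient-correlation similarity.
#' A derivative-free coordinate-wise local search (Powell-style step
#' halving) runs on a two-level image pyramid. Translation along the ray is
#' unobservable in a single orthographic view and is always kept at its
#' initial value; with `dof = "inplane"` (the default) the search covers the
#' well-conditioned subspace — rotation about the ray axis plus the two
#' detector-plane translations — while `dof = "full"` also searches the two
#' out-of-plane rotations, which are only second-order observable for
#' near-planar elongated anatomy and may drift at negligible similarity
#' cost. The documented capture range is roughly 10 mm / 10 deg; never
#' raises on non-convergence — returns the best pose found with
#' `converged = FALSE`.
#'
#' @param ct a [ct_volume()] (normalized).
#' @param label the paired [label_volume()].
#' @param target target [drr_image()] (an X-ray-like image; it is coarsely
#'   rescaled to \[0, 1\], which the similarity is invariant to anyway).
#' @param geom [projection_geometry()] matching the target.
#' @param init initial [rigid3d()] pose.
#' @param model [attenuation_model()].
#' @param step0 initial parameter step `c(deg, mm)`.
#' @param tol convergence tolerance on the parameter step `c(deg, mm)`.
#' @param max_iter cap on similarity evaluations.
#' @param dof "inplane" or "full" (see Details). In-plane mode requires the
#'   ray along an axis of the rotation parameterization (the default -Y
#'   view); otherwise full mode is used.
#' @return a `registration_result`.
#' @export
register <- function(ct, label, target, geom, init = rigid3d(),
                     model = attenuation_model(),
                     step0 = c(2, 2), tol = c(0.1, 0.1),
                     max_iter = 900, dof = c("inplane", "full")) {
  dof <- match.arg(dof)
  ray_axis <- which(abs(abs(geom$view_direction) - 1) < 1e-9)
  if (dof == "inplane" && length(ray_axis) != 1) dof <- "full"
  if (!same_geometry(ct, label)) stop("ct/label geometry mismatch")
  tgt <- if (is.matrix(target)) target else target$pixels
  rng <- range(tgt)
  if (diff(rng) > 0) tgt <- (tgt - rng[1]) / diff(rng)
  mu <- hu_to_mu(ct, model)
  mu$voxels[!(label$voxels %in% c(1, 2))] <- 0
  tgt_half <- half_image(tgt)
  geom_half <- projection_geometry(
    mode = geom$mode, view_direction = geom$view_direction,
    size = geom$size %/% 2L, spacing = geom$spacing * 2,
    center = geom$center, source_distance = geom$source_distance,
    step_length = geom$step_length)
  evals <- 0L
  uv <- detector_basis(geom$view_direction)
  par_to_tf <- function(par) {
    rigid3d(par[1:3],
            init$translation + par[4] * uv$u + par[5] * uv$v)
  }
  sim_at <- function(par, level) {
    evals <<- evals + 1L
    tf <- par_to_tf(par)
    img <- if (level == 1) render_drr(mu, geom_half, pose = tf)
           else render_drr(mu, geom, pose = tf)
    tryCatch(gradient_correlation(img$pixels,
                                  if (level == 1) tgt_half else tgt),
             error = function(e) -Inf)
  }
  par <- c(init$rotation, 0, 0)
  search <- if (dof == "inplane") c(ray_axis, 4L, 5L) else 1:5
  best <- -Inf
  for (level in 1:2) {
    step <- c(rep(step0[1] * (3 - level) / 2, 3),
              rep(step0[2] * (3 - level) / 2, 2))
    lim <- c(rep(tol[1], 3), rep(tol[2], 2))
    best <- sim_at(par, level)
    while (any(step[search] > lim[search] / 2) && evals < max_iter) {
      improved <- FALSE
      for (k in search) {
        for (sgn in c(1, -1)) {
          cand <- par
          cand[k] <- cand[k] + sgn * step[k]
          s <- sim_at(cand, level)
          if (s > best + 1e-10) {
            par <- cand; best <- s; improved <- TRUE
            break
          }
          if (evals >= max_iter) break
        }
        if (evals >= max_iter) break
      }
      if (!improved) step <- step / 2
    }
  }
  registration_result(par_to_tf(par), best, evals,
                      converged = evals < max_iter)
}

#' Render a registration-DRR
#'
#' The segmented-bone DRR at a registered pose: the paired "ground truth"
#' image the translation network is trained against.
#'
#' @param ct,label,geom,model as in [render_bone_drr()].
#' @param transform a [rigid3d()] (typically `register(...)$transform`).
#' @return a [drr_image()].
#' @export
make_registration_drr <- function(ct, label, transform, geom,
                                  model = attenuation_model()) {
  render_bone_drr(ct, label, geom, model, pose = transform)
}
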