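# Shared fixtures, memoized per test session. Everything is generated in
# code; nothing is read from disk.

.fixture_env <- new.env(parent = emptyenv())

# internal helpers used across tests
with_seed <- xray2bone:::with_seed
index_to_world <- xray2bone:::index_to_world

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# reference phantom rasterized on a small grid, with its normalized sample
ref_phantom <- function() {
  memo("ref_phantom", {
    spec <- reference_phantom_spec()
    ph <- rasterize_phantom(spec, phantom_grid(c(48, 48, 48), 2.5))
    frame <- build_frame(ph$landmarks)
    ns <- normalize_volume(ph$ct, ph$label, frame, shape = c(24, 24, 24))
    list(spec = spec, ph = ph, frame = frame, ns = ns)
  })
}

desk_geom <- function() {
  projection_geometry(size = c(32, 32), spacing = c(2.5, 2.5),
                      step_length = 2)
}

# exhaustive double-loop ASD oracle (kept deliberately naive)
asd_exhaustive <- function(A, B) {
  if (!is.matrix(A)) A <- A$points
  if (!is.matrix(B)) B <- B$points
  da <- apply(A, 1, function(p) min(sqrt(colSums((t(B) - p)^2))))
  db <- apply(B, 1, function(p) min(sqrt(colSums((t(A) - p)^2))))
  (sum(da) + sum(db)) / (nrow(A) + nrow(B))
}

# homogeneous sphere attenuation volume embedded with an empty margin so the
# trilinear interpolant covers the full solid; boundary voxels carry their
# partial-volume fraction (2^3 subsamples) so the fixture itself does not
# dominate the oracle error
sphere_mu <- function(r_mm = 10, spacing = 0.5, mu = 0.02) {
  n <- ceiling(2 * r_mm / spacing) + 9
  g <- grid3d(rep(n, 3), spacing)
  xs <- g$origin[1] + (seq_len(n) - 1) * spacing
  vox <- array(0, rep(n, 3))
  for (ox in c(-0.25, 0.25)) for (oy in c(-0.25, 0.25))
    for (oz in c(-0.25, 0.25)) {
      pts2 <- outer(outer((xs + ox * spacing)^2, (xs + oy * spacing)^2, `+`),
                    (xs + oz * spacing)^2, `+`)
      vox <- vox + (pts2 <= r_mm^2) * (mu / 8)
    }
  structure(list(voxels = vox, spacing = g$spacing, origin = g$origin,
                 orientation = diag(3)),
            class = "mu_volume")
}

# tiny translator pair set: degraded vs clean bone DRR of posed phantoms
toy_pairs <- function(n = 8, seed = 42) {
  memo(sprintf("toy_pairs_%d_%d", n, seed), {
    rp <- ref_phantom()
    geom <- desk_geom()
    lapply(seq_len(n), function(i) {
      pose <- with_seed(seed + i, rigid3d(
        rotation = c(0, stats::runif(1, -5, 5), 0),
        translation = c(stats::runif(1, -5, 5), 0, stats::runif(1, -5, 5))))
      bone <- render_bone_drr(rp$ns$ct, rp$ns$label, geom, pose = pose)
      full <- render_drr(hu_to_mu(rp$ns$ct), geom, pose = pose)
      xr <- degrade_to_xray(full, degradation_params(seed = seed + i),
                            bone_drr = bone)
      list(xray = xr, drr = bone)
    })
  })
}
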