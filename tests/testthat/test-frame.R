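canonical_truth <- function(spec, shape = c(64, 64, 64), fov = 40) {
  # phantom rasterized directly on the canonical grid (no resampling):
  # canonical coordinates are spec coordinates shifted to the frame origin
  fr0 <- build_frame(phantom_landmarks(spec))
  cg <- canonical_grid(shape, fov)
  rasterize_phantom(spec, grid3d(cg$shape, cg$spacing, cg$origin),
                    pose = rigid3d(translation = -fr0$origin))
}

test_that("canonical landmarks yield the identity frame", {
  lm <- phantom_landmarks(phantom_spec())
  fr <- build_frame(lm)
  expect_equal(fr$x_axis, c(1, 0, 0), tolerance = 1e-9)
  expect_equal(fr$y_axis, c(0, 1, 0), tolerance = 1e-9)
  expect_equal(fr$z_axis, c(0, 0, 1), tolerance = 1e-9)
  # origin sits on the shaft axis at the articular surface
  expect_equal(fr$origin, lm$articular_surface_point, tolerance = 1e-9)
})

test_that("frames are equivariant under rigid transforms of the landmarks", {
  lm <- phantom_landmarks(sample_phantom_spec(5))
  f1 <- build_frame(lm)
  for (s in 1:5) {
    tf <- with_seed(s, rigid3d(rotation = stats::runif(3, -40, 40),
                               translation = stats::runif(3, -20, 20)))
    lm2 <- landmark_set(rigid_apply(tf, lm$styloid_point),
                        rigid_apply(tf, lm$sigmoid_notch_point),
                        rigid_apply(tf, lm$shaft_axis_points),
                        rigid_apply(tf, lm$articular_surface_point))
    f2 <- build_frame(lm2)
    R <- rigid_rotation_matrix(tf)
    A1 <- cbind(f1$x_axis, f1$y_axis, f1$z_axis)
    A2 <- cbind(f2$x_axis, f2$y_axis, f2$z_axis)
    expect_lt(max(abs(A2 - R %*% A1)), 1e-6)
    expect_lt(max(abs(f2$origin - as.vector(rigid_apply(tf, f1$origin)))),
              1e-6)
    # orthonormal, right-handed
    expect_lt(max(abs(crossprod(A2) - diag(3))), 1e-6)
    expect_gt(det(A2), 0)
  }
})

test_that("degenerate reference line is rejected", {
  lm <- phantom_landmarks(phantom_spec())
  lm_bad <- landmark_set(c(0, 0, 0), c(0, 0, 30), lm$shaft_axis_points,
                         lm$articular_surface_point)
  expect_error(build_frame(lm_bad), "degenerate")
})

test_that("normalization with the identity frame reproduces the volume", {
  spec <- phantom_spec()
  fr0 <- build_frame(phantom_landmarks(spec))
  cg <- canonical_grid(c(32, 32, 32), 40)
  ph <- rasterize_phantom(spec, grid3d(cg$shape, cg$spacing, cg$origin),
                          pose = rigid3d(translation = -fr0$origin))
  ident <- anatomical_frame(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  ns <- normalize_volume(ph$ct, ph$label, ident, shape = c(32, 32, 32))
  expect_equal(ns$ct$voxels, ph$ct$voxels, tolerance = 1e-10)
  expect_identical(ns$label$voxels, ph$label$voxels)
})

test_that("nearest-neighbour label resampling introduces no new classes", {
  spec <- sample_phantom_spec(2)
  ph <- rasterize_phantom(spec, phantom_grid(c(64, 64, 64), 1.5))
  ns <- normalize_volume(ph$ct, ph$label, build_frame(ph$landmarks),
                         shape = c(24, 24, 24))
  expect_true(all(ns$label$voxels %in% unique(as.vector(ph$label$voxels))))
  expect_true(all(dim(ns$label$voxels) == c(24, 24, 24)))
  # grid spans exactly +/- 40 mm about the origin along Z
  zmin <- ns$label$origin[3]
  zmax <- zmin + (dim(ns$label$voxels)[3] - 1) * ns$label$spacing[3]
  expect_equal(zmin + zmax, 0, tolerance = 1e-9)
  expect_equal(zmax - zmin, 80 - ns$label$spacing[3], tolerance = 1e-9)
})

test_that("posed phantoms normalize back to canonical (label round trip)", {
  set.seed(11)
  for (s in 1:4) {
    spec <- sample_phantom_spec(s)
    gt <- canonical_truth(spec)
    pose <- rigid3d(rotation = stats::runif(3, -15, 15),
                    translation = stats::runif(3, -8, 8))
    ph <- rasterize_phantom(spec, phantom_grid(c(100, 100, 100), 1),
                            pose = pose)
    ns <- normalize_volume(ph$ct, ph$label, build_frame(ph$landmarks),
                           shape = c(64, 64, 64))
    expect_gt(label_dice(ns$label, gt$label, 1), 0.95)
  }
})

test_that("normalized bone DRRs are pose-invariant up to resampling error", {
  spec <- sample_phantom_spec(3)
  geom <- projection_geometry(size = c(32, 32), spacing = 2.5,
                              step_length = 1.25)
  imgs <- lapply(1:2, function(s) {
    pose <- with_seed(40 + s, rigid3d(rotation = stats::runif(3, -15, 15),
                                      translation = stats::runif(3, -8, 8)))
    ph <- rasterize_phantom(spec, phantom_grid(c(100, 100, 100), 1),
                            pose = pose)
    ns <- normalize_volume(ph$ct, ph$label, build_frame(ph$landmarks),
                           shape = c(48, 48, 48))
    render_bone_drr(ns$ct, ns$label, geom)
  })
  rms <- sqrt(mean((imgs[[1]]$pixels - imgs[[2]]$pixels)^2))
  expect_lt(rms / max(imgs[[2]]$pixels), 0.05)
})
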