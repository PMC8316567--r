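test_that("HU to attenuation follows the affine map with clipping", {
  m <- attenuation_model(mu_water = 0.02, global_scale = 1)
  v <- ct_volume(array(c(0, -1000, 1000, 2000), c(4, 2, 2)), spacing = 1)
  mu <- hu_to_mu(v, m)
  expect_equal(mu$voxels[1, 1, 1], 0.02)        # water
  expect_equal(mu$voxels[2, 1, 1], 0)           # air
  expect_equal(mu$voxels[3, 1, 1], 2 * 0.02)    # HU 1000
  expect_equal(mu$voxels[4, 1, 1], 3 * 0.02)
  m2 <- attenuation_model(mu_water = 0.02, global_scale = 0.5)
  expect_equal(hu_to_mu(v, m2)$voxels, mu$voxels * 0.5)
})

test_that("all-zero attenuation renders an all-zero image", {
  mu <- structure(list(voxels = array(0, c(8, 8, 8)), spacing = c(1, 1, 1),
                       origin = rep(-3.5, 3), orientation = diag(3)),
                  class = "mu_volume")
  img <- render_drr(mu, projection_geometry(size = c(6, 6), spacing = 1,
                                            step_length = 0.5))
  expect_true(all(img$pixels == 0))
})

test_that("homogeneous slab integrates to mu * thickness within 1%", {
  # slab of 20 material planes embedded with empty margins
  n <- 30
  vox <- array(0, c(n, n, n))
  vox[, 6:25, ] <- 0.02
  mu <- structure(list(voxels = vox, spacing = c(1, 1, 1),
                       origin = rep(-(n - 1) / 2, 3), orientation = diag(3)),
                  class = "mu_volume")
  img <- render_drr(mu, projection_geometry(size = c(8, 8), spacing = 1,
                                            step_length = 0.25))
  expect_lt(max(abs(img$pixels - 0.02 * 20)) / (0.02 * 20), 0.01)
})

test_that("homogeneous sphere matches the chord-length closed form", {
  mu <- sphere_mu(r_mm = 10, spacing = 0.5, mu = 0.02)
  geom <- projection_geometry(size = c(81, 81), spacing = 0.25,
                              step_length = 0.2)
  img <- render_drr(mu, geom)
  us <- (seq_len(81) - 41) * 0.25
  d2 <- outer(us^2, us^2, `+`)
  ok <- d2 <= (0.8 * 10)^2
  expected <- 0.02 * 2 * sqrt(pmax(100 - d2, 0))
  rel <- abs(img$pixels[ok] - expected[ok]) / expected[ok]
  expect_lt(max(rel), 0.02)
})

test_that("rendering is linear in attenuation", {
  mu <- sphere_mu(r_mm = 8, spacing = 1, mu = 0.01)
  geom <- projection_geometry(size = c(16, 16), spacing = 1.5,
                              step_length = 0.5)
  a <- render_drr(mu, geom)
  mu3 <- mu
  mu3$voxels <- mu$voxels * 3
  b <- render_drr(mu3, geom)
  expect_equal(b$pixels, 3 * a$pixels, tolerance = 1e-12)
})

test_that("halving the step length barely changes the sphere image", {
  mu <- sphere_mu(r_mm = 10, spacing = 1, mu = 0.02)
  g1 <- projection_geometry(size = c(32, 32), spacing = 1, step_length = 1)
  g2 <- projection_geometry(size = c(32, 32), spacing = 1, step_length = 0.5)
  a <- render_drr(mu, g1)
  b <- render_drr(mu, g2)
  rms <- sqrt(mean((a$pixels - b$pixels)^2)) / max(b$pixels)
  expect_lt(rms, 0.005)
})

test_that("too-coarse step length is refused", {
  mu <- sphere_mu(r_mm = 5, spacing = 0.5)
  expect_error(render_drr(mu, projection_geometry(size = c(8, 8),
                                                  spacing = 2,
                                                  step_length = 1)),
               "step_length")
})

test_that("bone DRR equals masking non-bone voxels to air", {
  rp <- ref_phantom()
  geom <- desk_geom()
  bone <- render_bone_drr(rp$ph$ct, rp$ph$label, geom)
  # two-path equivalence
  ct2 <- rp$ph$ct
  ct2$voxels[!(rp$ph$label$voxels %in% 1:2)] <- -1000
  direct <- render_drr(hu_to_mu(ct2), geom)
  expect_equal(bone$pixels, direct$pixels, tolerance = 1e-10)
  # monotone masking
  full <- render_drr(hu_to_mu(rp$ph$ct), geom)
  expect_true(all(bone$pixels <= full$pixels + 1e-12))
  # all-background label renders zero
  empty <- label_volume(array(0L, dim(rp$ph$label$voxels)),
                        spacing = rp$ph$label$spacing,
                        origin = rp$ph$label$origin)
  z <- render_bone_drr(rp$ph$ct, empty, geom)
  expect_true(all(z$pixels == 0))
  # mismatched geometry is a pairing error
  shr <- label_volume(array(0L, c(8, 8, 8)), spacing = 1)
  expect_error(render_bone_drr(rp$ph$ct, shr, geom), "mismatch")
})

test_that("default calibration puts the reference bone DRR near 0.20", {
  rp <- ref_phantom()
  img <- render_bone_drr(rp$ph$ct, rp$ph$label, desk_geom())
  expect_gte(max(img$pixels), 0.10)
  expect_lte(max(img$pixels), 0.30)
})

test_that("perspective projection converges to orthographic at distance", {
  mu <- sphere_mu(r_mm = 8, spacing = 1, mu = 0.02)
  go <- projection_geometry(size = c(16, 16), spacing = 1.5,
                            step_length = 0.5)
  gp <- projection_geometry(mode = "perspective", size = c(16, 16),
                            spacing = 1.5, step_length = 0.5,
                            source_distance = 5000)
  a <- render_drr(mu, go)
  b <- render_drr(mu, gp)
  expect_lt(max(abs(a$pixels - b$pixels)), 0.02 * max(a$pixels) + 1e-6)
})
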