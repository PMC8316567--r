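test_that("phantom spec sampling is deterministic and respects bounds", {
  pop <- phantom_population()
  a <- sample_phantom_spec(7, pop)
  b <- sample_phantom_spec(7, pop)
  expect_identical(a, b)
  expect_false(identical(a, sample_phantom_spec(8, pop)))

  # degenerate population collapses to the point
  pop0 <- lapply(pop, function(r) rep(mean(r), 2))
  s <- sample_phantom_spec(1, pop0)
  expect_equal(s$radius_params$length, mean(pop$radius_length))
  expect_equal(s$inter_bone_gap, mean(pop$inter_bone_gap))

  # inverted bounds raise
  bad <- pop
  bad$radius_length <- c(60, 50)
  expect_error(sample_phantom_spec(1, bad), "inverted")
})

test_that("sampled parameters match the population mean (Monte Carlo)", {
  pop <- phantom_population()
  draws <- vapply(1:100, function(s) {
    sp <- sample_phantom_spec(s, pop)
    c(sp$radius_params$length, sp$ulna_params$r_shaft, sp$inter_bone_gap)
  }, numeric(3))
  check <- function(vals, r) {
    se <- diff(r) / sqrt(12) / sqrt(ncol(draws))
    expect_lt(abs(mean(vals) - mean(r)), 3 * se)
  }
  check(draws[1, ], pop$radius_length)
  check(draws[2, ], pop$ulna_r_shaft)
  check(draws[3, ], pop$inter_bone_gap)
})

test_that("phantom spec invariants are enforced", {
  expect_error(phantom_spec(inter_bone_gap = 0), "inter_bone_gap")
  expect_error(phantom_spec(cortical_thickness = -1), "positive")
  expect_error(phantom_spec(hu_levels = c(air = 0, soft = -10,
                                          trabecular = 300, cortical = 1200)),
               "ordered")
})

test_that("rasterization produces exact background HU and consistent labels", {
  spec <- phantom_spec()
  ph <- rasterize_phantom(spec, phantom_grid(c(64, 64, 64), 1.5))
  expect_true(all(ph$label$voxels %in% 0:2))
  expect_true(any(ph$label$voxels == 1) && any(ph$label$voxels == 2))
  # voxels outside the soft-tissue envelope carry air HU exactly
  corner <- ph$ct$voxels[1:3, 1:3, 1:3]
  expect_true(all(corner == spec$hu_levels[["air"]]))
  # bone voxels carry bone HU
  expect_true(all(ph$ct$voxels[ph$label$voxels > 0] %in%
                    spec$hu_levels[c("trabecular", "cortical")]))
  expect_true(all(dim(ph$ct$voxels) == dim(ph$label$voxels)))
})

test_that("radius label volume matches the closed-form solid volume", {
  for (s in c(3, 11)) {
    spec <- sample_phantom_spec(s)
    ph <- rasterize_phantom(spec, phantom_grid(c(96, 96, 96), 1))
    vox <- sum(ph$label$voxels == 1) * prod(ph$ct$spacing)
    expect_lt(abs(vox - phantom_bone_volumes(spec)[["radius"]]) /
                phantom_bone_volumes(spec)[["radius"]], 0.05)
  }
})

test_that("bones keep their specified clearance and landmarks sit on anatomy", {
  for (s in 1:5) {
    spec <- sample_phantom_spec(s)
    ph <- rasterize_phantom(spec, phantom_grid(c(64, 64, 64), 1.5))
    ctr <- voxel_centers(ph$label)
    pr <- ctr[as.vector(ph$label$voxels == 1), , drop = FALSE]
    pu <- ctr[as.vector(ph$label$voxels == 2), , drop = FALSE]
    gap_measured <- min(xray2bone:::.nn_min_dist_cpp(pr, pu))
    expect_gte(gap_measured,
               spec$inter_bone_gap - 2 * max(ph$label$spacing))
    # styloid tip within one voxel of the radius label
    d_sty <- min(xray2bone:::.nn_min_dist_cpp(
      matrix(ph$landmarks$styloid_point, 1), pr))
    expect_lte(d_sty, max(ph$label$spacing) * sqrt(3))
  }
})

test_that("oversized phantoms are refused with the offending extent", {
  expect_error(rasterize_phantom(phantom_spec(),
                                 grid3d(c(16, 16, 16), 1)),
               "exceeds grid")
})

test_that("degradation honors identity settings and is seed-deterministic", {
  rp <- ref_phantom()
  full <- render_drr(hu_to_mu(rp$ns$ct), desk_geom())
  ident <- degradation_params(soft_tissue_weight = 1, noise_sigma = 0,
                              gamma = 1, vignette_strength = 0, seed = 1)
  expect_equal(degrade_to_xray(full, ident)$pixels, full$pixels)
  p <- degradation_params(noise_sigma = 0.05, seed = 9)
  expect_identical(degrade_to_xray(full, p)$pixels,
                   degrade_to_xray(full, p)$pixels)
  expect_error(degradation_params(noise_sigma = -1), "noise_sigma")
})

test_that("degradation noise has the configured standard deviation", {
  img <- drr_image(matrix(0.3, 256, 256))
  p0 <- degradation_params(noise_sigma = 0, gamma = 1.3,
                           vignette_strength = 0.2, seed = 5)
  p1 <- degradation_params(noise_sigma = 0.02, gamma = 1.3,
                           vignette_strength = 0.2, seed = 5)
  base <- degrade_to_xray(img, p0)
  noisy <- degrade_to_xray(img, p1)
  expect_lt(abs(stats::sd(noisy$pixels - base$pixels) - 0.02) / 0.02, 0.05)
})
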