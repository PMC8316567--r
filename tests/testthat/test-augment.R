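test_that("3D augmentation yields exactly factor items within stated ranges", {
  rp <- ref_phantom()
  items <- augment_3d(rp$ns, factor = 5, rot_range = 10, trans_range = 10,
                      seed = 3, geom = desk_geom())
  expect_length(items, 5)
  draws <- t(vapply(items, function(it)
    c(it$transform$rotation, it$transform$translation), numeric(6)))
  expect_true(all(abs(draws) <= 10 + 1e-12))
  # deterministic in seed
  again <- augment_3d(rp$ns, factor = 5, rot_range = 10, trans_range = 10,
                      seed = 3, geom = desk_geom())
  expect_identical(draws, t(vapply(again, function(it)
    c(it$transform$rotation, it$transform$translation), numeric(6))))
  expect_error(augment_3d(rp$ns, factor = 0), "factor")
})

test_that("large draws stay inside the configured uniform bounds", {
  draws <- with_seed(1, matrix(stats::runif(1000 * 6, -1, 1), 1000, 6))
  # the augmenter scales unit draws by the range; verify through the API on
  # a batch large enough to probe the bounds
  rp <- ref_phantom()
  items <- augment_3d(rp$ns, factor = 40, rot_range = 30, trans_range = 30,
                      seed = 9, geom = desk_geom())
  vals <- unlist(lapply(items, function(it)
    c(it$transform$rotation, it$transform$translation)))
  expect_true(all(abs(vals) <= 30))
  expect_gt(max(abs(vals)), 20)  # ranges are actually exercised
})

test_that("zero ranges give identity transforms and the unaugmented DRR", {
  rp <- ref_phantom()
  geom <- desk_geom()
  items <- augment_3d(rp$ns, factor = 2, rot_range = 0, trans_range = 0,
                      seed = 1, geom = geom)
  base <- render_bone_drr(rp$ns$ct, rp$ns$label, geom)
  for (it in items) {
    expect_equal(it$transform$rotation, c(0, 0, 0))
    expect_equal(it$drr$pixels, base$pixels, tolerance = 1e-10)
    # target label is the unposed normalized label
    expect_identical(it$label$voxels, rp$ns$label$voxels)
  }
})

test_that("2D pair augmentation preserves pairing and count", {
  pairs <- toy_pairs(4)
  out <- augment_2d_pairs(pairs, factor = 5, seed = 2)
  expect_length(out, 20)
  expect_equal(vapply(out, `[[`, 0, "source"),
               rep(1:4, each = 5))
  # identity ranges reproduce the inputs
  id <- augment_2d_pairs(pairs, factor = 2,
                         ranges = list(trans = 0, rot = 0,
                                       scale = c(1, 1), shear = 0),
                         seed = 1)
  expect_equal(id[[1]]$xray$pixels, pairs[[1]]$xray$pixels,
               tolerance = 1e-10)
  expect_equal(id[[1]]$drr$pixels, pairs[[1]]$drr$pixels, tolerance = 1e-10)
  # mismatched member shapes are a pairing error
  bad <- list(list(xray = drr_image(matrix(0, 8, 8)),
                   drr = drr_image(matrix(0, 9, 9))))
  expect_error(augment_2d_pairs(bad, 2), "share shape")
})

test_that("the recorded affine inverts back to the original image", {
  pairs <- toy_pairs(2)
  out <- augment_2d_pairs(pairs, factor = 3,
                          ranges = list(trans = 4, rot = 8,
                                        scale = c(0.95, 1.05), shear = 4),
                          seed = 5)
  for (k in c(2, 5)) {
    src <- pairs[[out[[k]]$source]]$xray$pixels
    back <- warp_image(out[[k]]$xray, out[[k]]$transform, inverse = TRUE)
    # compare away from the border (warping fills outside with 0)
    inner <- 6:27
    rms <- sqrt(mean((back$pixels[inner, inner] - src[inner, inner])^2))
    expect_lt(rms / diff(range(src)), 0.02)
  }
})

test_that("patient-level split is disjoint, exhaustive and leak-free", {
  ids <- sprintf("pt%02d", 1:8)
  sp <- make_split(ids, folds = 4, val_frac = 0.15, seed = 1)
  test_sets <- lapply(sp$plan, `[[`, "test")
  expect_equal(sort(unlist(test_sets)), sort(ids))
  expect_equal(vapply(test_sets, length, 0L), rep(2L, 4))
  for (f in seq_along(sp$plan)) {
    p <- sp$plan[[f]]
    expect_length(intersect(p$train, p$validation), 0)
    expect_length(intersect(p$train, p$test), 0)
    expect_length(intersect(p$validation, p$test), 0)
    expect_setequal(c(p$train, p$validation, p$test), ids)
  }
  expect_identical(sp, make_split(ids, folds = 4, val_frac = 0.15, seed = 1))
  expect_error(make_split(ids[1:3], folds = 4), "fewer patients")
})

test_that("augmented items from one patient stay on one side of the divide", {
  ids <- sprintf("pt%02d", 1:12)
  sp <- make_split(ids, folds = 4, val_frac = 0.2, seed = 3)
  # simulate augmented items tagged by patient
  items <- rep(ids, each = 7)
  for (p in sp$plan) {
    train_items <- items[items %in% p$train]
    val_items <- items[items %in% p$validation]
    expect_length(intersect(unique(train_items), unique(val_items)), 0)
  }
})
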