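test_that("MAE matches hand arithmetic", {
  a <- matrix(c(0, 0.4, 0.2, 0.6), 2)
  b <- matrix(0.1, 2, 2)
  expect_equal(mae(a, a), 0)
  expect_equal(mae(matrix(0, 2, 2), matrix(1, 2, 2)), 1)
  expect_equal(mae(a, b), mean(c(0.1, 0.3, 0.1, 0.5)))
  expect_error(mae(a, matrix(0, 3, 3)), "share shape")
})

test_that("surface extraction respects geometry", {
  # single isolated voxel: a closed shell centered on the voxel
  v <- array(0L, c(9, 9, 9))
  v[5, 5, 5] <- 1L
  lab <- label_volume(v, spacing = 2)
  s <- surface_from_label(lab, 1)
  ctr_true <- index_to_world(lab, matrix(c(4, 4, 4), 1))
  expect_lt(max(abs(colMeans(s$points) - ctr_true)), 1)  # half a voxel
  expect_equal(nrow(s$points), 6)
  # solid sphere: surface points at the nominal radius within a voxel
  n <- 33
  g <- array(0L, c(n, n, n))
  idx <- as.matrix(expand.grid(1:n, 1:n, 1:n)) - (n + 1) / 2
  g[rowSums(idx^2) <= 100] <- 1L
  lab2 <- label_volume(g, spacing = 1)
  s2 <- surface_from_label(lab2, 1)
  ctr <- index_to_world(lab2, matrix(rep((n - 1) / 2, 3), 1))
  d <- sqrt(rowSums(sweep(s2$points, 2, ctr)^2))
  expect_true(all(abs(d - 10) <= 1))
  # all points inside volume bounds + 1 voxel
  expect_true(all(s2$points >= lab2$origin - 1 &
                    s2$points <= -lab2$origin + 1))
  expect_error(surface_from_label(lab2, 2), "empty")
})

test_that("spatial-index ASD equals the exhaustive oracle exactly", {
  for (s in 1:20) {
    ab <- with_seed(s, list(A = matrix(stats::runif(600, -10, 10), 200),
                            B = matrix(stats::runif(600, -10, 10), 200)))
    expect_lt(abs(asd(ab$A, ab$B) - asd_exhaustive(ab$A, ab$B)), 1e-9)
  }
  A <- with_seed(99, matrix(stats::rnorm(300), 100))
  expect_equal(asd(A, A), 0)
  B <- with_seed(98, matrix(stats::rnorm(300), 100))
  expect_lt(abs(asd(A, B) - asd(B, A)), 1e-12)
  expect_error(asd(A, matrix(numeric(0), 0, 3)), "non-empty")
})

test_that("ASD is invariant under joint rigid motion", {
  ab <- with_seed(5, list(A = matrix(stats::runif(300), 100),
                          B = matrix(stats::runif(450), 150)))
  base <- asd(ab$A, ab$B)
  for (s in 1:3) {
    tf <- with_seed(s, rigid3d(stats::runif(3, -90, 90),
                               stats::runif(3, -30, 30)))
    expect_lt(abs(asd(rigid_apply(tf, ab$A), rigid_apply(tf, ab$B)) - base),
              1e-9)
  }
})

test_that("ASD of a translated cube converges to the brute-force value", {
  cube <- function(n, shift = 0) {
    g <- as.matrix(expand.grid(seq(0, 1, length.out = n),
                               seq(0, 1, length.out = n),
                               seq(0, 1, length.out = n)))
    on_face <- apply(g, 1, function(p) any(p == 0 | p == 1))
    sweep(g[on_face, ], 2, c(shift, 0, 0), `+`)
  }
  for (n in c(6, 10)) {
    A <- cube(n)
    B <- cube(n, shift = 0.25)
    expect_lt(abs(asd(A, B) - asd_exhaustive(A, B)), 1e-9)
  }
})

test_that("histogram matching reshapes the within-mask distribution", {
  set.seed(2)
  xr <- matrix(stats::runif(64 * 64), 64)^2
  tmpl <- matrix(stats::rbeta(64 * 64, 2, 5), 64)
  mask <- matrix(TRUE, 64, 64)
  mask[1:10, ] <- FALSE
  out <- histogram_match_baseline(xr, tmpl, mask)
  expect_true(all(out$pixels[!mask] == 0))
  ks <- suppressWarnings(stats::ks.test(out$pixels[mask],
                                        tmpl[mask]))$statistic
  expect_lt(ks, 0.05)
  # matching an image to itself over a full mask is the identity
  idm <- histogram_match_baseline(xr, xr, matrix(TRUE, 64, 64))
  expect_lt(max(abs(idm$pixels - xr)), 0.02)
  expect_error(histogram_match_baseline(xr, tmpl, matrix(FALSE, 64, 64)),
               "empty")
  expect_error(histogram_match_baseline(xr, tmpl, matrix(TRUE, 2, 2)),
               "mask shape")
})

test_that("experiment reports are complete and aggregates recompute", {
  # miniature reconstruction state: train a tiny TL net on structured data
  ds <- with_seed(7, {
    n <- 8; V <- 5^3
    Y <- matrix(0L, n, V)
    arr_idx <- as.matrix(expand.grid(1:5, 1:5, 1:5))
    for (i in seq_len(n)) {
      Y[i, rowSums(sweep(arr_idx, 2, c(2, 3, 3))^2) <= 2] <- 1L
      Y[i, rowSums(sweep(arr_idx, 2, c(4, 3, 3))^2) <= 1] <- 2L
    }
    list(X = matrix(stats::runif(n * 9), n, 9), Y = Y,
         grid = list(dim = c(5, 5, 5), spacing = rep(1, 3),
                     origin = rep(-2, 3)),
         x_scale = 1, shape2d = c(3, 3))
  })
  cfg <- tlnet_config(latent = 6, enc_hidden = 8, dec_hidden = 8,
                      pred_hidden = 8, iters = c(300, 300, 50), batch = 4,
                      lrs = c(1e-3, 1e-3, 1e-4), seed = 3)
  st <- train_tlnet(ds, cfg)
  truth <- label_volume(array(ds$Y[1, ], c(5, 5, 5)), spacing = 1,
                        origin = rep(-2, 3))
  img <- drr_image(matrix(ds$X[1, ], 3, 3))
  cases <- list(c1 = list(images = list(condA = img, condB = img),
                          truth = truth, reference = img))
  rep1 <- run_experiment(cases, c("condA", "condB"), st)
  expect_equal(nrow(rep1$rows), 4)  # 2 conditions x 2 bones
  expect_setequal(rep1$rows$bone, c("radius", "ulna"))
  for (i in seq_len(nrow(rep1$aggregates))) {
    ag <- rep1$aggregates[i, ]
    sub <- rep1$rows[rep1$rows$condition == ag$condition &
                       rep1$rows$bone == ag$bone & !is.na(rep1$rows$asd_mm), ]
    expect_equal(ag$mean_asd, mean(sub$asd_mm), tolerance = 1e-9)
  }
  expect_error(run_experiment(cases, c("condA", "missing"), st), "lacks")
})
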