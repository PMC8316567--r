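# independent forward oracle: explicit matrix arithmetic, no package
# forward-pass code
oracle_forward <- function(p, inp) {
  h <- pmax(inp %*% p$W1 + matrix(p$b1, nrow(inp), length(p$b1),
                                  byrow = TRUE), 0)
  h %*% p$W2 + matrix(p$b2, nrow(h), length(p$b2), byrow = TRUE)
}

toy_params <- function(seed = 3) {
  cfg <- tlnet_config(latent = 2, enc_hidden = 2, dec_hidden = 2,
                      pred_hidden = 2, classes = 2, seed = seed)
  tl_init_params(1, 2, cfg)
}

test_that("cross entropy matches closed forms", {
  # uniform logits over 3 classes
  expect_equal(label_loss(matrix(0, 5, 3), c(0L, 1L, 2L, 1L, 0L)), log(3),
               tolerance = 1e-12)
  # saturated logits vanish
  lg <- matrix(-1e4, 4, 3)
  lg[cbind(1:4, c(1, 2, 3, 1))] <- 1e4
  expect_lt(label_loss(lg, c(0L, 1L, 2L, 0L)), 1e-4)
  # 2-voxel, 2-class toy against hand arithmetic
  logits <- c(0.3, -0.1, 0.2, 0.5)  # class-block layout
  p1 <- exp(0.3) / (exp(0.3) + exp(0.2))
  p2 <- exp(0.5) / (exp(-0.1) + exp(0.5))
  expect_equal(label_loss(matrix(logits, 1), matrix(c(0L, 1L), 1)),
               -(log(p1) + log(p2)) / 2, tolerance = 1e-6)
  expect_error(label_loss(matrix(0, 2, 3), c(0L, 5L)), "class")
})

test_that("stage losses match an independent matrix-arithmetic oracle", {
  p <- toy_params()
  yn <- c(0.9, 0.2)
  y <- 0L
  z <- oracle_forward(p$E, matrix(yn, 1))
  lg <- oracle_forward(p$D, z)
  ce <- -log(exp(lg[1]) / sum(exp(lg)))
  expect_equal(loss_step1(y, yn, p, 1e-4), ce + 1e-4 * sum(abs(z)),
               tolerance = 1e-6)
  expect_equal(loss_step1(y, yn, p, 0), ce, tolerance = 1e-6)

  x <- c(0.5, -0.3)
  zp <- oracle_forward(p$P, matrix(x, 1))
  lg2 <- oracle_forward(p$D, zp)
  ce2 <- -log(exp(lg2[1]) / sum(exp(lg2)))
  p2 <- tl_freeze(p, "D")
  expect_equal(loss_step2(x, y, p2, 1e-4), ce2 + 1e-4 * sum(abs(zp)),
               tolerance = 1e-6)

  p3 <- tl_freeze(p, "E")
  # lambda2 = 0 removes the consistency term: step3 equals step2
  expect_equal(loss_step3(x, y, p3, 1e-4, 0),
               loss_step2(x, y, p2, 1e-4), tolerance = 1e-12)
  pr <- exp(lg2 - max(lg2)); pr <- pr / sum(pr)
  Ey <- oracle_forward(p$E, matrix(c(1, 0), 1))
  Eh <- oracle_forward(p$E, pr)
  expect_equal(loss_step3(x, y, p3, 1e-4, 1e-4),
               ce2 + 1e-4 * sum(abs(zp)) + 1e-4 * sqrt(sum((Ey - Eh)^2)),
               tolerance = 1e-6)
  expect_gte(loss_step3(x, y, p3, 1e-4, 1e-4), 0)
})

test_that("latent zeroing kills the regularizer", {
  p <- toy_params()
  # force E to output zeros
  p$E$W2[] <- 0
  p$E$b2[] <- 0
  l0 <- loss_step1(0L, c(1, 0), p, 0)
  l1 <- loss_step1(0L, c(1, 0), p, 100)
  expect_equal(l0, l1, tolerance = 1e-12)
})

test_that("stage losses enforce freezing contracts", {
  p <- toy_params()
  expect_error(loss_step2(c(0, 0), 0L, p), "frozen")
  expect_error(loss_step3(c(0, 0), 0L, p), "frozen")
})

test_that("one-hot encoding is exact and noise is seed-deterministic", {
  oh <- one_hot_label(c(0L, 2L, 1L), classes = 3)
  expect_equal(matrix(oh, 3), rbind(c(1, 0, 0), c(0, 0, 1), c(0, 1, 0)))
  n1 <- one_hot_label(c(0L, 1L), classes = 3, noise_sigma = 0.1, seed = 4)
  n2 <- one_hot_label(c(0L, 1L), classes = 3, noise_sigma = 0.1, seed = 4)
  expect_identical(n1, n2)
})

small_train_ds <- function(n = 6, V = 4^3, npix = 16) {
  # tiny structured dataset: class-1 blob whose extent varies with x
  with_seed(31, {
    X <- matrix(stats::runif(n * npix), n, npix)
    Y <- matrix(0L, n, V)
    for (i in seq_len(n)) Y[i, seq_len(8 + 4 * (i %% 3))] <- 1L
    list(X = X, Y = Y,
         grid = list(dim = c(4, 4, 4), spacing = rep(1, 3),
                     origin = rep(0, 3)),
         x_scale = 1, shape2d = c(4, 4))
  })
}

test_that("three-stage training runs, logs and freezes correctly", {
  ds <- small_train_ds()
  cfg <- tlnet_config(latent = 4, enc_hidden = 6, dec_hidden = 6,
                      pred_hidden = 6, iters = c(2, 2, 2), batch = 3,
                      seed = 8)
  st <- train_tlnet(ds, cfg)
  expect_length(st$logs$stage1, 2)
  expect_length(st$logs$stage2, 2)
  expect_length(st$logs$stage3, 2)
  expect_true(all(st$stages_done))
  expect_true(st$freeze_checks$stage2_decoder)
  expect_true(st$freeze_checks$stage3_encoder)
  # reconstruct is deterministic and well-typed
  x <- matrix(0.5, 4, 4)
  r1 <- reconstruct(x, st)
  r2 <- reconstruct(x, st)
  expect_identical(r1$voxels, r2$voxels)
  expect_true(all(r1$voxels %in% 0:2))
  expect_error(reconstruct(matrix(0, 5, 5), st), "shape")
})

test_that("stage-1 loss descends on a learnable dataset", {
  ds <- small_train_ds(n = 12)
  cfg <- tlnet_config(latent = 8, enc_hidden = 12, dec_hidden = 12,
                      pred_hidden = 12, iters = c(250, 5, 5), batch = 6,
                      lrs = c(1e-3, 1e-4, 1e-5), seed = 2)
  st <- train_tlnet(ds, cfg)
  expect_lt(mean(tail(st$logs$stage1, 10)), st$logs$stage1[1])
})

test_that("raising lambda1 100x shrinks the predictor latent norm", {
  ds <- small_train_ds(n = 12)
  base <- tlnet_config(latent = 8, enc_hidden = 12, dec_hidden = 12,
                       pred_hidden = 12, iters = c(150, 300, 5), batch = 6,
                       lrs = c(1e-3, 1e-3, 1e-5), lambda1 = 1e-4, seed = 2)
  hi <- base
  hi$lambda1 <- 1e-2
  st_lo <- train_tlnet(ds, base)
  st_hi <- train_tlnet(ds, hi)
  zn <- function(st) {
    Z <- xray2bone:::tl_predict(st$params, ds$X)
    mean(rowSums(abs(Z)))
  }
  expect_lt(zn(st_hi), zn(st_lo))
})

test_that("reconstruction requires a trained predictor", {
  st <- structure(list(stages_done = c(stage1 = TRUE, stage2 = FALSE,
                                       stage3 = FALSE)),
                  class = "tlnet_state")
  expect_error(reconstruct(matrix(0, 4, 4), st), "predictor")
})
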