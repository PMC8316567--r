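#' TL-embedding network configuration
#'
#' The reconstruction network has three parts: a 3D label autoencoder
#' (encoder E, decoder D) over one-hot bone labels, and a 2D predictor P
#' mapping a DRR into the autoencoder's latent space so that `D(P(x))`
#' reconstructs the 3D label. Training proceeds in three stages:
#' (1) denoising autoencoder on labels with Gaussian noise on the one-hot
#' input, (2) predictor with the decoder frozen, (3) fine-tuning of
#' predictor and decoder with the encoder frozen and a latent-consistency
#' term. Stage losses:
#' \deqn{L_1 = L_{label}(D(E(y_n)), y) + \lambda_1 |E(y_n)|_1}
#' \deqn{L_2 = L_{label}(D(P(x)), y) + \lambda_1 |P(x)|_1}
#' \deqn{L_3 = L_2 + \lambda_2 |E(y) - E(D(P(x)))|_2}
#' with \eqn{L_{label}} the softmax cross entropy (mean over voxels),
#' \eqn{|.|_1} the sum of absolute latent entries and \eqn{|.|_2} the
#' (unsquared) Euclidean norm; `norm = "l2sq"` switches to the squared norm.
#'
#' @param latent latent dimension (default 64).
#' @param enc_hidden,dec_hidden,pred_hidden hidden widths.
#' @param classes voxel classes (3: background, radius, ulna).
#' @param lambda1 L1 latent regularization weight (default 1e-4).
#' @param lambda2 latent-consistency weight (default 1e-4).
#' @param noise_sigma Gaussian noise s.d. on the one-hot input (default 0.1).
#' @param iters length-3 update counts per stage (clinical-scale protocol:
#'   35000, 35000, 15000).
#' @param lrs length-3 Adam learning rates (1e-4, 1e-4, 1e-5).
#' @param batch minibatch size.
#' @param norm latent-consistency norm: "l2" (Euclidean, the default) or
#'   "l2sq".
#' @param latent_consistency "decoded" compares `E(y)` with `E(D(P(x)))`
#'   (decoder output re-encoded, softmax probabilities fed to E);
#'   "predictor" compares `E(y)` with `P(x)` directly.
#' @param seed integer seed.
#' @return object of class `tlnet_config`.
#' @export
tlnet_config <- function(latent = 64, enc_hidden = 96, dec_hidden = 96,
                         pred_hidden = 96, classes = 3,
                         lambda1 = 1e-4, lambda2 = 1e-4,
                         noise_sigma = 0.1,
                         iters = c(35000, 35000, 15000),
                         lrs = c(1e-4, 1e-4, 1e-5),
                         batch = 8,
                         norm = c("l2", "l2sq"),
                         latent_consistency = c("decoded", "predictor"),
                         seed = 0L) {
  norm <- match.arg(norm)
  latent_consistency <- match.arg(latent_consistency)
  if (lambda1 < 0 || lambda2 < 0) stop("lambda1 and lambda2 must be >= 0")
  if (classes < 2) stop("need at least 2 classes")
  if (length(iters) != 3 || any(iters < 1))
    stop("iters must be three counts >= 1")
  structure(list(latent = latent, enc_hidden = enc_hidden,
                 dec_hidden = dec_hidden, pred_hidden = pred_hidden,
                 classes = as.integer(classes), lambda1 = lambda1,
                 lambda2 = lambda2, noise_sigma = noise_sigma,
                 iters = as.integer(iters), lrs = lrs,
                 batch = as.integer(batch), norm = norm,
                 latent_consistency = latent_consistency,
                 seed = as.integer(seed)),
            class = "tlnet_config")
}

#' Initialize TL-net parameters
#'
#' @param n_voxels voxels per label volume (V).
#' @param n_pixels pixels per DRR.
#' @param cfg a [tlnet_config()].
#' @return parameter set: list with sublists `E`, `D`, `P`, a `frozen`
#'   character vector, and dimension bookkeeping.
#' @export
tl_init_params <- function(n_voxels, n_pixels, cfg = tlnet_config()) {
  C <- cfg$classes
  list(E = nn_init_dense(c(n_voxels * C, cfg$enc_hidden, cfg$latent),
                         derive_seed(cfg$seed, 11)),
       D = nn_init_dense(c(cfg$latent, cfg$dec_hidden, n_voxels * C),
                         derive_seed(cfg$seed, 12)),
       P = nn_init_dense(c(n_pixels, cfg$pred_hidden, cfg$latent),
                         derive_seed(cfg$seed, 13)),
       frozen = character(0),
       V = as.integer(n_voxels), C = C, npix = as.integer(n_pixels))
}

#' Flag a subnetwork as frozen
#' @param params a TL-net parameter set.
#' @param which one of "E", "D", "P".
#' @export
tl_freeze <- function(params, which) {
  stopifnot(which %in% c("E", "D", "P"))
  params$frozen <- union(params$frozen, which)
  params
}

# ---- forwards -------------------------------------------------------------

tl_encode <- function(params, Yn) nn_forward(params$E, Yn, 2)$out
tl_decode <- function(params, Z) nn_forward(params$D, Z, 2)$out
tl_predict <- function(params, X) nn_forward(params$P, X, 2)$out

# coerce a label argument to an integer class vector
as_label_vec <- function(y) {
  if (inherits(y, "label_volume")) return(as.integer(y$voxels))
  as.integer(as.vector(y))
}

#' One-hot encode a label volume, optionally with Gaussian noise
#'
#' @param y a [label_volume()] or integer vector of classes 0..C-1.
#' @param classes number of classes C.
#' @param noise_sigma Gaussian noise s.d. added to the encoding.
#' @param seed noise seed.
#' @return numeric vector of length `V * C` (class-block layout).
#' @export
one_hot_label <- function(y, classes = 3, noise_sigma = 0, seed = 0L) {
  yv <- as_label_vec(y)
  if (any(yv < 0 | yv >= classes)) stop("label class outside {0..C-1}")
  V <- length(yv)
  out <- numeric(V * classes)
  out[seq_len(V) + yv * V] <- 1
  if (noise_sigma > 0)
    out <- out + with_seed(seed, stats::rnorm(V * classes, 0, noise_sigma))
  out
}

#' Softmax cross-entropy label loss
#'
#' Mean over voxels of the negative log softmax probability of the true
#' class.
#'
#' @param logits per-voxel class scores: a `V x C` matrix, a vector of
#'   length `V * C` in class-block layout, or a batch matrix `n x (V * C)`.
#' @param y [label_volume()] / integer classes (length V), or an `n x V`
#'   integer matrix matching a batch of logits.
#' @return scalar loss (mean over voxels, and over the batch if batched).
#' @export
label_loss <- function(logits, y) {
  if (is.matrix(y)) {   # batch
    V <- ncol(y)
    C <- ncol(logits) / V
    return(ce_loss_blocks(logits, y, V, C)$loss)
  }
  yv <- as_label_vec(y)
  V <- length(yv)
  if (is.matrix(logits) && nrow(logits) == V) {
    C <- ncol(logits)
    lg <- matrix(as.vector(logits), 1, V * C)
  } else {
    lg <- matrix(as.vector(logits), 1)
    C <- ncol(lg) / V
  }
  if (C != round(C) || C < 2) stop("logits shape does not match label")
  if (any(yv < 0 | yv >= C)) stop("label class outside {0..C-1}")
  ce_loss_blocks(lg, matrix(yv, 1), V, as.integer(C))$loss
}

# batched softmax cross entropy over class blocks; returns loss and the
# gradient wrt logits (already divided by n*V)
ce_loss_blocks <- function(logits, Y, V, C) {
  n <- nrow(logits)
  arr <- array(logits, c(n * V, C))
  mx <- arr[, 1]
  for (c in 2:C) mx <- pmax(mx, arr[, c])
  ex <- exp(arr - mx)
  s <- rowSums(ex)
  yv <- as.integer(as.vector(Y))          # n*V values, column-major = per
  # logits rows stack as (sample, voxel); Y is n x V so as.vector matches
  true_col <- yv + 1L
  idx <- seq_len(n * V) + (true_col - 1L) * (n * V)
  logp_true <- (arr[idx] - mx) - log(s)
  probs <- ex / s
  grad <- probs
  grad[idx] <- grad[idx] - 1
  list(loss = -mean(logp_true),
       grad = array(grad / (n * V), c(n, V * C)),
       probs = array(probs, c(n, V * C)))
}

# gradient of sum over voxels of f(softmax) wrt logits, given gradient wrt
# probabilities (both n x V*C)
softmax_backward_blocks <- function(dprobs, probs, V, C) {
  n <- nrow(probs)
  dp <- array(dprobs, c(n * V, C))
  p <- array(probs, c(n * V, C))
  dot <- rowSums(dp * p)
  array(p * (dp - dot), c(n, V * C))
}

latent_penalty <- function(Z, lambda1) lambda1 * sum(abs(Z)) / nrow(Z)

consistency_norm <- function(Ediff, norm) {
  nrms <- sqrt(rowSums(Ediff^2))
  if (norm == "l2") mean(nrms) else mean(nrms^2)
}

# ---- stage losses (pure functions, used by tests and by training) ---------

#' Stage-1 loss (denoising autoencoder)
#'
#' `L = label_loss(D(E(y_noised)), y) + lambda1 * |E(y_noised)|_1`.
#'
#' @param y label: [label_volume()], integer vector, or `n x V` matrix.
#' @param y_noised noisy one-hot input: vector `V * C` or matrix
#'   `n x (V * C)`.
#' @param params from [tl_init_params()].
#' @param lambda1 L1 weight.
#' @return scalar loss.
#' @export
loss_step1 <- function(y, y_noised, params, lambda1 = 1e-4) {
  Yn <- if (is.matrix(y_noised)) y_noised else matrix(y_noised, 1)
  Ym <- if (is.matrix(y)) y else matrix(as_label_vec(y), 1)
  if (ncol(Yn) != params$V * params$C) stop("y_noised shape mismatch")
  Z <- tl_encode(params, Yn)
  logits <- tl_decode(params, Z)
  ce_loss_blocks(logits, Ym, params$V, params$C)$loss +
    latent_penalty(Z, lambda1)
}

#' Stage-2 loss (predictor, decoder frozen)
#'
#' `L = label_loss(D(P(x)), y) + lambda1 * |P(x)|_1`; requires the decoder
#' to be flagged frozen (gradient flows to P only).
#'
#' @param x DRR pixels: vector `npix` or matrix `n x npix`.
#' @inheritParams loss_step1
#' @export
loss_step2 <- function(x, y, params, lambda1 = 1e-4) {
  if (!("D" %in% params$frozen))
    stop("stage-2 loss requires the decoder to be frozen (tl_freeze(params, 'D'))")
  X <- if (is.matrix(x)) x else matrix(x, 1)
  Ym <- if (is.matrix(y)) y else matrix(as_label_vec(y), 1)
  Z <- tl_predict(params, X)
  logits <- tl_decode(params, Z)
  ce_loss_blocks(logits, Ym, params$V, params$C)$loss +
    latent_penalty(Z, lambda1)
}

#' Stage-3 loss (fine-tuning with latent consistency, encoder frozen)
#'
#' `L = label_loss(D(P(x)), y) + lambda1 * |P(x)|_1 +
#'  lambda2 * |E(y) - E(D(P(x)))|_2`; requires the encoder to be flagged
#' frozen (gradient flows to P and D only). The decoder output is re-encoded
#' through its softmax probabilities; `latent_consistency = "predictor"` in
#' the config switches the second operand to `P(x)`.
#'
#' @inheritParams loss_step2
#' @param lambda2 latent-consistency weight.
#' @param norm "l2" (Euclidean, default) or "l2sq".
#' @param latent_consistency "decoded" or "predictor".
#' @export
loss_step3 <- function(x, y, params, lambda1 = 1e-4, lambda2 = 1e-4,
                       norm = "l2", latent_consistency = "decoded") {
  if (!("E" %in% params$frozen))
    stop("stage-3 loss requires the encoder to be frozen (tl_freeze(params, 'E'))")
  X <- if (is.matrix(x)) x else matrix(x, 1)
  Ym <- if (is.matrix(y)) y else matrix(as_label_vec(y), 1)
  Z <- tl_predict(params, X)
  logits <- tl_decode(params, Z)
  ce <- ce_loss_blocks(logits, Ym, params$V, params$C)
  Y1 <- t(vapply(seq_len(nrow(Ym)), function(i)
    one_hot_label(Ym[i, ], params$C), numeric(params$V * params$C)))
  Ey <- tl_encode(params, Y1)
  Ehat <- if (latent_consistency == "decoded")
    tl_encode(params, ce$probs) else Z
  ce$loss + latent_penalty(Z, lambda1) +
    lambda2 * consistency_norm(Ey - Ehat, norm)
}

# ---- training -------------------------------------------------------------

#' Build a TL-net training dataset from augmented items
#'
#' Flattens DRR/label pairs into matrices and records the canonical grid and
#' the dataset-level intensity scale used to normalize inputs to \[0, 1\].
#'
#' @param items list of `list(drr, label)` (e.g. from [augment_3d()]).
#' @param groups optional grouping vector (patient ids) per item.
#' @return list with `X` (n x npix), `Y` (n x V integer), `grid` metadata,
#'   `x_scale`, `shape2d`, `groups`.
#' @export
tlnet_dataset <- function(items, groups = NULL) {
  stopifnot(length(items) >= 1)
  X <- t(vapply(items, function(it) as.vector(it$drr$pixels),
                numeric(length(items[[1]]$drr$pixels))))
  x_scale <- max(X, 1e-8)
  Y <- t(vapply(items, function(it) as.integer(it$label$voxels),
                integer(length(items[[1]]$label$voxels))))
  l1 <- items[[1]]$label
  list(X = X / x_scale, Y = Y,
       grid = list(dim = dim(l1$voxels), spacing = l1$spacing,
                   origin = l1$origin),
       x_scale = x_scale,
       shape2d = dim(items[[1]]$drr$pixels),
       groups = groups %||% seq_along(items))
}

#' Train the TL-embedding network (three stages)
#'
#' Runs the three training stages with their configured update counts and
#' learning rates under Adam: (1) denoising label autoencoder, (2) predictor
#' with frozen decoder, (3) predictor + decoder with frozen encoder and the
#' latent-consistency term. Frozen parameter sets are verified bitwise
#' identical across their stage and the checks are recorded in the state.
#'
#' @param dataset from [tlnet_dataset()] (training rows).
#' @param cfg a [tlnet_config()].
#' @param val optional validation dataset (monitored, never trained on).
#' @return object of class `tlnet_state`: `params`, per-stage loss logs,
#'   stage completion flags, freeze checks, grid and scale metadata.
#' @export
train_tlnet <- function(dataset, cfg = tlnet_config(), val = NULL) {
  n <- nrow(dataset$X)
  if (n < 1) stop("empty training dataset")
  V <- ncol(dataset$Y)
  C <- cfg$classes
  params <- tl_init_params(V, ncol(dataset$X), cfg)
  logs <- list()
  flags <- c(stage1 = FALSE, stage2 = FALSE, stage3 = FALSE)
  freeze_checks <- list()
  onehot_batch <- function(Yb, sigma, C) {
    nb <- nrow(Yb); Vb <- ncol(Yb)
    oh <- matrix(0, nb, Vb * C)
    idx <- rep(seq_len(nb), Vb) +
      (rep(seq_len(Vb), each = nb) - 1L + as.vector(Yb) * Vb) * nb
    oh[idx] <- 1
    if (sigma > 0) oh <- oh + matrix(stats::rnorm(nb * Vb * C, 0, sigma),
                                     nb, Vb * C)
    oh
  }

  # ---- stage 1: denoising autoencoder ----
  optE <- adam_init(params$E)
  optD <- adam_init(params$D)
  loss1 <- numeric(cfg$iters[1])
  with_seed(derive_seed(cfg$seed, 21), {
    for (it in seq_len(cfg$iters[1])) {
      ids <- sample.int(n, min(cfg$batch, n))
      Yb <- dataset$Y[ids, , drop = FALSE]
      Yn <- onehot_batch(Yb, cfg$noise_sigma, C)
      fE <- nn_forward(params$E, Yn, 2)
      Z <- fE$out
      fD <- nn_forward(params$D, Z, 2)
      ce <- ce_loss_blocks(fD$out, Yb, V, C)
      loss1[it] <- ce$loss + latent_penalty(Z, cfg$lambda1)
      if (!is.finite(loss1[it]))
        stop(sprintf("NaN loss at stage 1, step %d", it))
      bD <- nn_backward(params$D, fD, ce$grad, 2)
      dZ <- bD$input + cfg$lambda1 * sign(Z) / nrow(Z)
      bE <- nn_backward(params$E, fE, dZ, 2, need_input = FALSE)
      upE <- adam_step(params$E, bE, optE, cfg$lrs[1])
      params$E <- upE$params; optE <- upE$state
      upD <- adam_step(params$D, bD, optD, cfg$lrs[1])
      params$D <- upD$params; optD <- upD$state
    }
  })
  check_finite_params(c(params$E, params$D), "stage 1")
  logs$stage1 <- loss1
  flags["stage1"] <- TRUE

  # ---- stage 2: predictor, decoder frozen ----
  params <- tl_freeze(params, "D")
  D_before <- params$D
  optP <- adam_init(params$P)
  loss2 <- numeric(cfg$iters[2])
  with_seed(derive_seed(cfg$seed, 22), {
    for (it in seq_len(cfg$iters[2])) {
      ids <- sample.int(n, min(cfg$batch, n))
      Xb <- dataset$X[ids, , drop = FALSE]
      Yb <- dataset$Y[ids, , drop = FALSE]
      fP <- nn_forward(params$P, Xb, 2)
      Z <- fP$out
      fD <- nn_forward(params$D, Z, 2)
      ce <- ce_loss_blocks(fD$out, Yb, V, C)
      loss2[it] <- ce$loss + latent_penalty(Z, cfg$lambda1)
      if (!is.finite(loss2[it]))
        stop(sprintf("NaN loss at stage 2, step %d", it))
      bD <- nn_backward(params$D, fD, ce$grad, 2)
      dZ <- bD$input + cfg$lambda1 * sign(Z) / nrow(Z)
      bP <- nn_backward(params$P, fP, dZ, 2, need_input = FALSE)
      upP <- adam_step(params$P, bP, optP, cfg$lrs[2])
      params$P <- upP$params; optP <- upP$state
    }
  })
  check_finite_params(params$P, "stage 2")
  freeze_checks$stage2_decoder <- identical(params$D, D_before)
  logs$stage2 <- loss2
  flags["stage2"] <- TRUE

  # ---- stage 3: predictor + decoder, encoder frozen ----
  params$frozen <- setdiff(params$frozen, "D")
  params <- tl_freeze(params, "E")
  E_before <- params$E
  optP3 <- adam_init(params$P)
  optD3 <- adam_init(params$D)
  loss3 <- numeric(cfg$iters[3])
  with_seed(derive_seed(cfg$seed, 23), {
    for (it in seq_len(cfg$iters[3])) {
      ids <- sample.int(n, min(cfg$batch, n))
      Xb <- dataset$X[ids, , drop = FALSE]
      Yb <- dataset$Y[ids, , drop = FALSE]
      nb <- length(ids)
      fP <- nn_forward(params$P, Xb, 2)
      Z <- fP$out
      fD <- nn_forward(params$D, Z, 2)
      ce <- ce_loss_blocks(fD$out, Yb, V, C)
      Y1 <- onehot_batch(Yb, 0, C)
      Ey <- tl_encode(params, Y1)
      dlogits <- ce$grad
      cons <- 0
      if (cfg$lambda2 > 0 && cfg$latent_consistency == "decoded") {
        fEh <- nn_forward(params$E, ce$probs, 2)
        diff <- Ey - fEh$out
        nrms <- sqrt(rowSums(diff^2))
        cons <- if (cfg$norm == "l2") mean(nrms) else mean(nrms^2)
        dEh <- if (cfg$norm == "l2")
          -cfg$lambda2 * diff / pmax(nrms, 1e-8) / nb
        else
          -2 * cfg$lambda2 * diff / nb
        bEh <- nn_backward(params$E, fEh, dEh, 2)
        dprobs <- bEh$input
        dlogits <- dlogits + softmax_backward_blocks(dprobs, ce$probs, V, C)
      } else if (cfg$lambda2 > 0) {
        diff <- Ey - Z
        nrms <- sqrt(rowSums(diff^2))
        cons <- if (cfg$norm == "l2") mean(nrms) else mean(nrms^2)
      }
      loss3[it] <- ce$loss + latent_penalty(Z, cfg$lambda1) +
        cfg$lambda2 * cons
      if (!is.finite(loss3[it]))
        stop(sprintf("NaN loss at stage 3, step %d", it))
      bD <- nn_backward(params$D, fD, dlogits, 2)
      dZ <- bD$input + cfg$lambda1 * sign(Z) / nrow(Z)
      if (cfg$lambda2 > 0 && cfg$latent_consistency == "predictor") {
        diffPZ <- Z - Ey
        dZ <- dZ + if (cfg$norm == "l2")
          cfg$lambda2 * diffPZ / pmax(sqrt(rowSums(diffPZ^2)), 1e-8) / nb
        else 2 * cfg$lambda2 * diffPZ / nb
      }
      bP <- nn_backward(params$P, fP, dZ, 2, need_input = FALSE)
      upP <- adam_step(params$P, bP, optP3, cfg$lrs[3])
      params$P <- upP$params; optP3 <- upP$state
      upD <- adam_step(params$D, bD, optD3, cfg$lrs[3])
      params$D <- upD$params; optD3 <- upD$state
    }
  })
  check_finite_params(c(params$P, params$D), "stage 3")
  freeze_checks$stage3_encoder <- identical(params$E, E_before)
  logs$stage3 <- loss3
  flags["stage3"] <- TRUE

  structure(list(params = params, logs = logs, stages_done = flags,
                 freeze_checks = freeze_checks, cfg = cfg,
                 grid = dataset$grid, x_scale = dataset$x_scale,
                 shape2d = dataset$shape2d),
            class = "tlnet_state")
}

#' Reconstruct a 3D bone label from a single DRR-like image
#'
#' `argmax` over the class scores of `D(P(x))`; deterministic given the
#' state.
#'
#' @param x a [drr_image()] (or matrix) with the training shape.
#' @param state a `tlnet_state` from [train_tlnet()].
#' @return a [label_volume()] on the canonical grid.
#' @export
reconstruct <- function(x, state) {
  if (!inherits(state, "tlnet_state") || !state$stages_done["stage2"])
    stop("predictor not trained: reconstruct needs a state past stage 2")
  px <- if (is.matrix(x)) x else x$pixels
  if (!all(dim(px) == state$shape2d))
    stop("input shape does not match the training DRR shape")
  X <- matrix(as.vector(px) / state$x_scale, 1)
  Z <- tl_predict(state$params, X)
  logits <- tl_decode(state$params, Z)
  V <- state$params$V; C <- state$params$C
  arr <- array(logits, c(V, C))
  cls <- max.col(arr, ties.method = "first") - 1L
  label_volume(array(as.integer(cls), state$grid$dim),
               spacing = state$grid$spacing, origin = state$grid$origin)
}
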