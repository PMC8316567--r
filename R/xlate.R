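#' Translator configuration
#'
#' Configuration of the paired conditional adversarial image translator
#' (pix2pix-style): a patch-based generator (a dense network applied
#' convolutionally to local patches, producing the clean segmented-bone DRR
#' pixel under each patch) trained against a patch discriminator on
#' (input, output) patch pairs, with a reconstruction (L1) term weighted far
#' above the adversarial term, following the conditional-adversarial
#' formulation this design descends from.
#'
#' @param patch_radius generator/discriminator receptive field radius in
#'   pixels (patch side `2r + 1`).
#' @param hidden generator hidden width.
#' @param disc_hidden discriminator hidden width.
#' @param l1_weight reconstruction (L1) weight, >= 0.
#' @param adv_weight adversarial weight, >= 0. At 0 the model reduces to
#'   supervised L1 regression.
#' @param epochs training epochs.
#' @param batch_images images per step.
#' @param adv_positions patch positions sampled per image for the
#'   adversarial terms.
#' @param lr,lr_disc Adam learning rates.
#' @param seed integer seed.
#' @return object of class `translator_config`.
#' @export
translator_config <- function(patch_radius = 3, hidden = 64,
                              disc_hidden = 32, l1_weight = 100,
                              adv_weight = 1, epochs = 12,
                              batch_images = 4, adv_positions = 64,
                              lr = 2e-3, lr_disc = 1e-3, seed = 0L) {
  if (l1_weight < 0 || adv_weight < 0) stop("loss weights must be >= 0")
  if (l1_weight == 0 && adv_weight == 0)
    stop("at least one of l1_weight/adv_weight must be > 0")
  stopifnot(patch_radius >= 1, hidden >= 1, epochs >= 1, batch_images >= 1)
  structure(list(patch_radius = patch_radius, hidden = hidden,
                 disc_hidden = disc_hidden, l1_weight = l1_weight,
                 adv_weight = adv_weight, epochs = epochs,
                 batch_images = batch_images, adv_positions = adv_positions,
                 lr = lr, lr_disc = lr_disc, seed = as.integer(seed)),
            class = "translator_config")
}

# neighbor index matrix: for each pixel (row) the flat index of each patch
# offset (column), NA outside the image
patch_index <- function(nu, nv, r) {
  ii <- rep.int(seq_len(nu), nv)
  jj <- rep(seq_len(nv), each = nu)
  offs <- expand.grid(du = -r:r, dv = -r:r)
  k <- nrow(offs)
  idx <- matrix(NA_integer_, nu * nv, k)
  for (o in seq_len(k)) {
    io <- ii + offs$du[o]
    jo <- jj + offs$dv[o]
    ok <- io >= 1 & io <= nu & jo >= 1 & jo <= nv
    idx[ok, o] <- io[ok] + (jo[ok] - 1L) * nu
  }
  idx
}

# im2col: npix x k patch matrix (zero padding)
extract_patches <- function(img_vec, pidx) {
  m <- matrix(0, nrow(pidx), ncol(pidx))
  ok <- !is.na(pidx)
  m[ok] <- img_vec[pidx[ok]]
  m
}

# normalized detector-position features (u, v in [-1, 1] and r^2): the
# generator is applied patchwise but must stay position-aware to undo
# position-dependent acquisition effects such as vignetting (the role the
# full-image receptive field plays in an encoder-decoder translator)
position_features <- function(nu, nv) {
  u <- rep.int(2 * (seq_len(nu) - (nu + 1) / 2) / nu, nv)
  v <- rep(2 * (seq_len(nv) - (nv + 1) / 2) / nv, each = nu)
  cbind(u, v, u^2 + v^2)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Train the paired image translator
#'
#' Alternating generator/discriminator updates on the conditional
#' adversarial + weighted L1 objective. Inputs and targets are normalized to
#' \[0, 1\] by dataset-level constants (recorded in the returned state, not
#' per image), so absolute intensity information survives translation.
#' Deterministic given the config seed (single-threaded BLAS assumed;
#' reproducible up to floating-point nondeterminism otherwise).
#'
#' @param pairs training pairs: list of `list(xray, drr)` ([drr_image()]s of
#'   one shared shape).
#' @param cfg a [translator_config()].
#' @param val_pairs validation pairs (raw, non-augmented); at least one.
#'   Validation images are never used in updates.
#' @return object of class `translator_state`: generator/discriminator
#'   parameters, normalization constants, and a per-epoch log with columns
#'   `epoch, l1, adv, disc, val_mae`.
#' @export
train_translator <- function(pairs, cfg = translator_config(),
                             val_pairs = list()) {
  if (length(pairs) < 1 || length(val_pairs) < 1)
    stop("need at least 1 training and 1 validation pair")
  shp <- dim(pairs[[1]]$xray$pixels)
  for (p in c(pairs, val_pairs))
    if (!all(dim(p$xray$pixels) == shp) || !all(dim(p$drr$pixels) == shp))
      stop("all pairs must share the training image shape")
  nu <- shp[1]; nv <- shp[2]; npix <- nu * nv
  r <- cfg$patch_radius
  k <- (2 * r + 1)^2
  pidx <- patch_index(nu, nv, r)
  sx <- max(1e-8, max(vapply(pairs, function(p) max(p$xray$pixels), 0)))
  sy <- max(1e-8, max(vapply(pairs, function(p) max(p$drr$pixels), 0)))
  X <- lapply(pairs, function(p) as.vector(p$xray$pixels) / sx)
  Y <- lapply(pairs, function(p) as.vector(p$drr$pixels) / sy)
  posf <- position_features(nu, nv)
  XP <- lapply(X, function(x) cbind(extract_patches(x, pidx), posf))
  G <- nn_init_dense(c(k + 3, cfg$hidden, 1), derive_seed(cfg$seed, 1))
  D <- nn_init_dense(c(2 * k, cfg$disc_hidden, 1), derive_seed(cfg$seed, 2))
  optG <- adam_init(G)
  optD <- adam_init(D)
  steps <- max(1, ceiling(length(pairs) / cfg$batch_images))
  log <- NULL
  state <- NULL
  with_seed(derive_seed(cfg$seed, 3), {
    for (epoch in seq_len(cfg$epochs)) {
      el1 <- eadv <- edisc <- 0
      for (step in seq_len(steps)) {
        ids <- sample.int(length(pairs), min(cfg$batch_images, length(pairs)))
        gl1 <- gadv <- dl <- 0
        gradsG <- lapply(G, function(p) p * 0)
        gradsD <- lapply(D, function(p) p * 0)
        for (id in ids) {
          xp <- XP[[id]]
          fwd <- nn_forward(G, xp, 2)
          yhat <- fwd$out[, 1]
          resid <- yhat - Y[[id]]
          l1 <- mean(abs(resid))
          dimg <- cfg$l1_weight * sign(resid) / npix
          advG <- 0
          if (cfg$adv_weight > 0) {
            pos <- sample.int(npix, min(cfg$adv_positions, npix))
            xpp <- xp[pos, seq_len(k), drop = FALSE]
            fake_in <- cbind(xpp, extract_patches(yhat, pidx)[pos, , drop = FALSE])
            real_in <- cbind(xpp, extract_patches(Y[[id]], pidx)[pos, , drop = FALSE])
            # generator: fool D on fake patches
            fD <- nn_forward(D, fake_in, 2)
            pfake <- sigmoid(fD$out[, 1])
            advG <- -mean(log(pmax(pfake, 1e-12)))
            dlogit <- matrix(cfg$adv_weight * (pfake - 1) / length(pos), ncol = 1)
            bD <- nn_backward(D, fD, dlogit, 2)
            dfake_y <- bD$input[, (k + 1):(2 * k), drop = FALSE]
            dsc <- scatter_patches2(dfake_y, pidx, pos, npix)
            dimg <- dimg + dsc
            # discriminator: real -> 1, fake -> 0 (fake detached)
            rD <- nn_forward(D, real_in, 2)
            preal <- sigmoid(rD$out[, 1])
            dl_id <- -mean(log(pmax(preal, 1e-12))) -
              mean(log(pmax(1 - pfake, 1e-12)))
            bDr <- nn_backward(D, rD, matrix((preal - 1) / length(pos), ncol = 1), 2)
            bDf <- nn_backward(D, fD, matrix(pfake / length(pos), ncol = 1), 2)
            for (nm in names(D))
              gradsD[[nm]] <- gradsD[[nm]] + bDr[[nm]] + bDf[[nm]]
            dl <- dl + dl_id
          }
          bG <- nn_backward(G, fwd, matrix(dimg, ncol = 1), 2, need_input = FALSE)
          for (nm in names(G)) gradsG[[nm]] <- gradsG[[nm]] + bG[[nm]]
          gl1 <- gl1 + l1
          gadv <- gadv + advG
        }
        nb <- length(ids)
        for (nm in names(G)) gradsG[[nm]] <- gradsG[[nm]] / nb
        if (!is.finite(gl1))
          stop(sprintf("NaN loss in L1 term at epoch %d", epoch))
        if (cfg$adv_weight > 0 && !is.finite(dl))
          stop(sprintf("NaN loss in adversarial term at epoch %d", epoch))
        up <- adam_step(G, gradsG, optG, cfg$lr)
        G <- up$params; optG <- up$state
        if (cfg$adv_weight > 0) {
          for (nm in names(D)) gradsD[[nm]] <- gradsD[[nm]] / nb
          upD <- adam_step(D, gradsD, optD, cfg$lr_disc)
          D <- upD$params; optD <- upD$state
        }
        el1 <- el1 + gl1 / nb
        eadv <- eadv + gadv / nb
        edisc <- edisc + dl / nb
      }
      check_finite_params(G, sprintf("translator epoch %d", epoch))
      st <- list(G = G, D = D, norm = list(sx = sx, sy = sy),
                 shape = shp, patch_radius = r, cfg = cfg)
      class(st) <- "translator_state"
      vm <- mean(vapply(val_pairs, function(p)
        mae(translate(p$xray, st), p$drr), numeric(1)))
      log <- rbind(log, data.frame(epoch = epoch, l1 = el1 / steps,
                                   adv = eadv / steps, disc = edisc / steps,
                                   val_mae = vm))
      state <- st
    }
  })
  state$log <- log
  state
}

# scatter for a subset of patch positions
scatter_patches2 <- function(dpatch, pidx, pos, npix) {
  g <- numeric(npix)
  sub <- pidx[pos, , drop = FALSE]
  for (o in seq_len(ncol(sub))) {
    ok <- !is.na(sub[, o])
    tg <- sub[ok, o]
    if (length(tg)) {
      agg <- rowsum(dpatch[ok, o], tg)
      ii <- as.integer(rownames(agg))
      g[ii] <- g[ii] + agg[, 1]
    }
  }
  g
}

#' Translate an X-ray-like image to a clean bone-DRR-like image
#'
#' Single deterministic forward pass of the trained generator; the output is
#' clipped at 0 and returned in original intensity units.
#'
#' @param xray a [drr_image()] with the training shape.
#' @param state a `translator_state` from [train_translator()].
#' @return a [drr_image()] ("GAN-DRR").
#' @export
translate <- function(xray, state) {
  px <- if (is.matrix(xray)) xray else xray$pixels
  if (!all(dim(px) == state$shape))
    stop(sprintf("input shape %s does not match training shape %s",
                 paste(dim(px), collapse = "x"),
                 paste(state$shape, collapse = "x")))
  pidx <- patch_index(state$shape[1], state$shape[2], state$patch_radius)
  xp <- cbind(extract_patches(as.vector(px) / state$norm$sx, pidx),
              position_features(state$shape[1], state$shape[2]))
  yhat <- nn_forward(state$G, xp, 2)$out[, 1] * state$norm$sy
  out <- matrix(pmax(yhat, 0), state$shape[1], state$shape[2])
  sp <- if (is.matrix(xray)) c(1, 1) else xray$spacing
  drr_image(out, spacing = sp)
}
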