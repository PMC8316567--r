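#' Pipeline configuration
#'
#' One nested configuration object driving the end-to-end demo: phantom
#' population and grids, projection geometry, augmentation, registration,
#' translator and TL-net settings, and the patient split. Every stage seed
#' is derived deterministically from the single `seed`. Two presets ship
#' with the package: `desk` (small grids, shortened training; the tested
#' path) and `paper` (the clinical-scale protocol: 400^3 volumes at
#' 0.625 mm, 500x625 images at 0.4 mm, augmentation factors 40 and 100 with
#' +/-30 deg / +/-30 mm, 35000/35000/15000 updates at learning rates
#' 1e-4/1e-4/1e-5, lambda1 = lambda2 = 1e-4, FOV +/-40 mm).
#'
#' @param preset "desk" or "paper", or a path to a YAML file.
#' @return object of class `pipeline_config` (a nested list).
#' @export
load_preset <- function(preset = "desk") {
  path <- if (file.exists(preset)) preset
          else system.file("presets", paste0(preset, ".yaml"),
                           package = "xray2bone")
  if (!nzchar(path) || !file.exists(path))
    stop(sprintf("no preset or config file '%s'", preset))
  cfg <- yaml::read_yaml(path)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' @param cfg a `pipeline_config`.
#' @return character vector of violations; empty when valid.
#' @export
validate_config <- function(cfg) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  num <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  if (!num(cfg$seed)) add("seed: must be a finite number")
  if (!num(cfg$n_phantoms) || cfg$n_phantoms < 4)
    add("n_phantoms: need at least 4")
  if (is.null(cfg$native_grid$shape) || any(cfg$native_grid$shape < 8))
    add("native_grid$shape: must be >= 8 per axis")
  if (!num(cfg$native_grid$spacing) || cfg$native_grid$spacing <= 0)
    add("native_grid$spacing: must be > 0")
  if (!num(cfg$fov_halfwidth) || cfg$fov_halfwidth <= 0)
    add("fov_halfwidth: must be > 0")
  if (!num(cfg$augment3d$factor) || cfg$augment3d$factor < 1)
    add("augment3d$factor: must be >= 1")
  if (!num(cfg$augment2d$factor) || cfg$augment2d$factor < 1)
    add("augment2d$factor: must be >= 1")
  if (!num(cfg$tlnet$lambda1) || cfg$tlnet$lambda1 < 0)
    add("tlnet$lambda1: must be >= 0")
  if (!num(cfg$tlnet$lambda2) || cfg$tlnet$lambda2 < 0)
    add("tlnet$lambda2: must be >= 0")
  if (length(cfg$tlnet$iters) != 3 || any(cfg$tlnet$iters < 1))
    add("tlnet$iters: must be three counts >= 1")
  if (length(cfg$tlnet$lrs) != 3 || any(cfg$tlnet$lrs <= 0))
    add("tlnet$lrs: must be three rates > 0")
  if (!num(cfg$translator$l1_weight) || cfg$translator$l1_weight < 0)
    add("translator$l1_weight: must be >= 0")
  if (!num(cfg$translator$adv_weight) || cfg$translator$adv_weight < 0)
    add("translator$adv_weight: must be >= 0")
  if (!num(cfg$split$folds) || cfg$split$folds < 2)
    add("split$folds: must be >= 2")
  if (!num(cfg$split$val_frac) || cfg$split$val_frac <= 0 ||
      cfg$split$val_frac >= 1)
    add("split$val_frac: must be in (0, 1)")
  if (!num(cfg$xray$noise_sigma) || cfg$xray$noise_sigma < 0)
    add("xray$noise_sigma: must be >= 0")
  if (!num(cfg$xray$gamma) || cfg$xray$gamma <= 0)
    add("xray$gamma: must be > 0")
  v
}

demo_geometry <- function(cfg) {
  fov <- cfg$fov_halfwidth
  sz <- unlist(cfg$drr$size)
  projection_geometry(size = sz,
                      spacing = c(2 * fov / sz[1], 2 * fov / sz[2]),
                      step_length = cfg$drr$step_length)
}

demo_model <- function(cfg) {
  attenuation_model(mu_water = cfg$attenuation$mu_water,
                    global_scale = cfg$attenuation$global_scale)
}

#' Run the end-to-end phantom demo
#'
#' Executes the full pipeline on procedurally generated phantoms: phantom
#' generation (randomly posed), anatomical normalization, 3D rigid
#' augmentation + TL-net three-stage training, X-ray-like image synthesis,
#' 2D-3D registration to obtain registration-DRRs, 2D affine augmentation +
#' translator training, and the four-condition evaluation (CT-DRR, GAN-DRR,
#' registration-DRR, bone-segmented histogram-matched X-ray) against
#' ground-truth labels on the held-out test patients.
#'
#' @param cfg a `pipeline_config` (see [load_preset()]).
#' @param out_dir optional output directory for manifests and reports; with
#'   `resume = TRUE`, completed stages found there are reloaded instead of
#'   recomputed.
#' @param resume reuse stage outputs present in `out_dir`.
#' @param verbose print stage progress.
#' @return list: `report` ([run_experiment()] result), `tl_state`,
#'   `xlate_state`, `split`, `registration` (per-case data.frame),
#'   `phantom_manifest`, `cfg`.
#' @export
run_demo <- function(cfg, out_dir = NULL, resume = TRUE, verbose = FALSE) {
  viol <- validate_config(cfg)
  if (length(viol))
    stop(paste(c("invalid pipeline config:", viol), collapse = "\n  "))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      f <- file.path(out_dir, paste0(name, ".rds"))
      if (resume && file.exists(f)) {
        say("stage %s: reusing %s", name, f)
        return(readRDS(f))
      }
      val <- expr
      saveRDS(val, f)
      return(val)
    }
    expr
  }
  seed <- cfg$seed
  geom <- demo_geometry(cfg)
  model <- demo_model(cfg)
  grid <- grid3d(unlist(cfg$native_grid$shape), cfg$native_grid$spacing,
                 origin = c(-(unlist(cfg$native_grid$shape)[1] - 1) *
                              cfg$native_grid$spacing / 2,
                            -(unlist(cfg$native_grid$shape)[2] - 1) *
                              cfg$native_grid$spacing / 2,
                            -0.7 * (unlist(cfg$native_grid$shape)[3] - 1) *
                              cfg$native_grid$spacing))
  n <- cfg$n_phantoms
  ids <- sprintf("p%03d", seq_len(n))

  say("stage 1/6: phantoms + normalization (%d phantoms)", n)
  samples <- stage("samples", {
    lapply(seq_len(n), function(i) {
      s_i <- derive_seed(seed, 100 + i)
      spec <- sample_phantom_spec(s_i)
      pose <- with_seed(derive_seed(seed, 200 + i), rigid3d(
        rotation = stats::runif(3, -cfg$pose_range$rot, cfg$pose_range$rot),
        translation = stats::runif(3, -cfg$pose_range$trans,
                                   cfg$pose_range$trans)))
      ph <- rasterize_phantom(spec, grid, pose = pose)
      frame <- build_frame(ph$landmarks)
      ns <- normalize_volume(ph$ct, ph$label, frame,
                             fov_halfwidth = cfg$fov_halfwidth,
                             shape = unlist(cfg$canonical_shape),
                             xy_halfwidth = cfg$xy_halfwidth %||%
                               cfg$fov_halfwidth)
      # X-ray-like image at a small unknown pose offset (registration truth)
      # in-plane acquisition offset: rotation about the ray axis (-Y view)
      # and detector-plane translations; see register() on observability
      off <- with_seed(derive_seed(seed, 300 + i), rigid3d(
        rotation = c(0, stats::runif(1, -cfg$xray$offset_rot,
                                     cfg$xray$offset_rot), 0),
        translation = c(stats::runif(1, -cfg$xray$offset_trans,
                                     cfg$xray$offset_trans), 0,
                        stats::runif(1, -cfg$xray$offset_trans,
                                     cfg$xray$offset_trans))))
      full <- render_drr(hu_to_mu(ns$ct, model), geom, pose = off)
      bone <- render_bone_drr(ns$ct, ns$label, geom, model, pose = off)
      dp <- degradation_params(
        soft_tissue_weight = cfg$xray$soft_tissue_weight,
        noise_sigma = cfg$xray$noise_sigma, gamma = cfg$xray$gamma,
        vignette_strength = cfg$xray$vignette, seed = derive_seed(seed, 400 + i))
      xray <- degrade_to_xray(full, dp, bone_drr = bone)
      # bone segmentation of the X-ray (role of the manual segmentation,
      # the first dataset-construction step): the projected silhouette of
      # the true bone at the acquisition pose. Registration, translation
      # and the histogram baseline all consume the segmented radiograph.
      seg_mask <- bone$pixels > 0.02 * max(bone$pixels)
      seg_xray <- drr_image(xray$pixels * seg_mask, spacing = xray$spacing)
      list(id = ids[i], spec = spec, sample = ns, xray = xray,
           seg_xray = seg_xray, xray_pose = off, bone_drr_at_pose = bone,
           seg_mask = seg_mask)
    })
  })
  phantom_manifest <- data.frame(
    id = ids,
    radius_len = vapply(samples, function(s) s$spec$radius_params$length, 0),
    ulna_rot = vapply(samples, function(s) s$spec$ulna_axial_rotation, 0),
    xray_rot_x = vapply(samples, function(s) s$xray_pose$rotation[1], 0),
    xray_trans_x = vapply(samples, function(s) s$xray_pose$translation[1], 0))

  say("stage 2/6: patient split")
  split <- make_split(ids, folds = cfg$split$folds,
                      val_frac = cfg$split$val_frac,
                      seed = derive_seed(seed, 2))
  plan <- split$plan[[1]]
  xlate_ids <- plan$train[seq_len(min(cfg$xlate_patients, length(plan$train)))]
  tl_train_ids <- plan$train
  by_id <- stats::setNames(samples, ids)

  say("stage 3/6: 3D augmentation + TL-net training (%d train patients)",
      length(tl_train_ids))
  tl_state <- stage("tl_state", {
    items <- list()
    groups <- character(0)
    for (pid in tl_train_ids) {
      it <- augment_3d(by_id[[pid]]$sample, factor = cfg$augment3d$factor,
                       rot_range = cfg$augment3d$rot,
                       trans_range = cfg$augment3d$trans,
                       seed = derive_seed(seed, 500 + match(pid, ids)),
                       geom = geom, model = model, include_identity = TRUE)
      items <- c(items, it)
      groups <- c(groups, rep(pid, length(it)))
    }
    train_ds <- tlnet_dataset(items, groups)
    val_items <- lapply(plan$validation, function(pid)
      list(drr = render_bone_drr(by_id[[pid]]$sample$ct,
                                 by_id[[pid]]$sample$label, geom, model),
           label = by_id[[pid]]$sample$label))
    val_ds <- tlnet_dataset(val_items, plan$validation)
    val_ds$X <- val_ds$X * val_ds$x_scale / train_ds$x_scale
    val_ds$x_scale <- train_ds$x_scale
    tlcfg <- tlnet_config(
      latent = cfg$tlnet$latent, enc_hidden = cfg$tlnet$hidden,
      dec_hidden = cfg$tlnet$hidden, pred_hidden = cfg$tlnet$hidden,
      lambda1 = cfg$tlnet$lambda1, lambda2 = cfg$tlnet$lambda2,
      noise_sigma = cfg$tlnet$noise_sigma,
      iters = unlist(cfg$tlnet$iters), lrs = unlist(cfg$tlnet$lrs),
      batch = cfg$tlnet$batch, seed = derive_seed(seed, 3))
    train_tlnet(train_ds, tlcfg, val = val_ds)
  })

  say("stage 4/6: 2D-3D registration (%d patients)",
      length(union(xlate_ids, c(plan$validation, plan$test))))
  reg <- stage("registration", {
    need <- union(xlate_ids, c(plan$validation, plan$test))
    res <- lapply(need, function(pid) {
      s <- by_id[[pid]]
      r <- register(s$sample$ct, s$sample$label, s$seg_xray, geom,
                    model = model)
      err_rot <- max(abs(r$transform$rotation - s$xray_pose$rotation))
      err_tr <- max(abs(r$transform$translation - s$xray_pose$translation))
      list(id = pid, result = r,
           drr = make_registration_drr(s$sample$ct, s$sample$label,
                                       r$transform, geom, model),
           err_rot = err_rot, err_trans = err_tr)
    })
    stats::setNames(res, need)
  })
  registration <- data.frame(
    id = names(reg),
    similarity = vapply(reg, function(r) r$result$similarity, 0),
    converged = vapply(reg, function(r) r$result$converged, TRUE),
    err_rot_deg = vapply(reg, function(r) r$err_rot, 0),
    err_trans_mm = vapply(reg, function(r) r$err_trans, 0))

  say("stage 5/6: 2D augmentation + translator training (%d patients)",
      length(xlate_ids))
  xlate_state <- stage("xlate_state", {
    pairs <- lapply(xlate_ids, function(pid)
      list(xray = by_id[[pid]]$seg_xray, drr = reg[[pid]]$drr))
    aug <- augment_2d_pairs(pairs, factor = cfg$augment2d$factor,
                            ranges = list(trans = cfg$augment2d$trans,
                                          rot = cfg$augment2d$rot,
                                          scale = unlist(cfg$augment2d$scale),
                                          shear = cfg$augment2d$shear),
                            seed = derive_seed(seed, 4),
                            include_identity = TRUE)
    val_pairs <- lapply(plan$validation, function(pid)
      list(xray = by_id[[pid]]$seg_xray, drr = reg[[pid]]$drr))
    xcfg <- translator_config(
      patch_radius = cfg$translator$patch_radius,
      hidden = cfg$translator$hidden,
      l1_weight = cfg$translator$l1_weight,
      adv_weight = cfg$translator$adv_weight,
      epochs = cfg$translator$epochs,
      lr = cfg$translator$lr, seed = derive_seed(seed, 5))
    train_translator(lapply(aug, function(a) list(xray = a$xray, drr = a$drr)),
                     xcfg, val_pairs = val_pairs)
  })

  say("stage 6/6: four-condition evaluation (%d test patients)",
      length(plan$test))
  report <- stage("report", {
    cases <- lapply(plan$test, function(pid) {
      s <- by_id[[pid]]
      regdrr <- reg[[pid]]$drr
      list(images = list(
             ct_drr = render_bone_drr(s$sample$ct, s$sample$label, geom,
                                      model),
             gan_drr = translate(s$seg_xray, xlate_state),
             registration_drr = regdrr,
             histmatch = histogram_match_baseline(s$xray, regdrr,
                                                  s$seg_mask),
             xray = s$seg_xray),
           truth = s$sample$label,
           reference = regdrr)
    })
    names(cases) <- plan$test
    run_experiment(cases, c("ct_drr", "gan_drr", "registration_drr",
                            "histmatch"), tl_state)
  })
  if (!is.null(out_dir)) {
    utils::write.csv(phantom_manifest,
                     file.path(out_dir, "phantoms.csv"), row.names = FALSE)
    utils::write.csv(registration,
                     file.path(out_dir, "registration.csv"), row.names = FALSE)
    utils::write.csv(xlate_state$log,
                     file.path(out_dir, "translator_log.csv"),
                     row.names = FALSE)
    write_report(report, csv_path = file.path(out_dir, "report.csv"),
                 json_path = file.path(out_dir, "report.json"))
  }
  cases <- lapply(plan$test, function(pid) {
    s <- by_id[[pid]]
    list(xray = s$seg_xray, reference = reg[[pid]]$drr,
         gan_drr = translate(s$seg_xray, xlate_state))
  })
  names(cases) <- plan$test
  list(report = report, tl_state = tl_state, xlate_state = xlate_state,
       split = split, registration = registration,
       phantom_manifest = phantom_manifest, test_images = cases, cfg = cfg)
}
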