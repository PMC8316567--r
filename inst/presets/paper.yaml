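# Clinical-scale preset: the full-resolution protocol
# (400^3 volumes at 0.625 mm, 500x625 images at 0.4 mm, FOV +/-40 mm,
# augmentation 40x at +/-30 deg / +/-30 mm and 100x 2D affine,
# 35000/35000/15000 updates at learning rates 1e-4/1e-4/1e-5,
# lambda1 = lambda2 = 1e-4). Not a CI path: run at this scale only on
# hardware sized for it.
seed: 1
n_phantoms: 173
native_grid:
  shape: [400, 400, 400]
  spacing: 0.625
canonical_shape: [128, 128, 128]
fov_halfwidth: 40
xy_halfwidth: 40
pose_range:
  rot: 15
  trans: 8
drr:
  size: [500, 625]
  step_length: 0.4
attenuation:
  mu_water: 0.02
  global_scale: 0.285
xray:
  soft_tissue_weight: 1.0
  noise_sigma: 0.01
  gamma: 1.3
  vignette: 0.2
  offset_rot: 5
  offset_trans: 5
augment3d:
  factor: 40
  rot: 30
  trans: 30
augment2d:
  factor: 100
  trans: 10
  rot: 10
  scale: [0.9, 1.1]
  shear: 5
xlate_patients: 33
translator:
  patch_radius: 3
  hidden: 64
  l1_weight: 100
  adv_weight: 1
  epochs: 50
  lr: 0.002
tlnet:
  latent: 64
  hidden: 96
  lambda1: 1.0e-4
  lambda2: 1.0e-4
  noise_sigma: 0.1
  iters: [35000, 35000, 15000]
  lrs: [1.0e-4, 1.0e-4, 1.0e-5]
  batch: 8
split:
  folds: 4
  val_frac: 0.15
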