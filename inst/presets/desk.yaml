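# Desk-scale preset: small grids and shortened training so the full
# pipeline runs on one CPU in minutes. This is the tested configuration.
seed: 1
n_phantoms: 56
native_grid:
  shape: [48, 48, 48]
  spacing: 2.5
canonical_shape: [24, 24, 24]
fov_halfwidth: 40
xy_halfwidth: 40
pose_range:        # world pose of each phantom before normalization
  rot: 15          # deg
  trans: 8         # mm
drr:
  size: [32, 32]
  step_length: 2.0 # mm, <= smallest voxel spacing of the rendered volumes
attenuation:
  mu_water: 0.02   # 1/mm
  global_scale: 0.285
xray:              # degradation of the full DRR into an X-ray-like image
  soft_tissue_weight: 1.0
  noise_sigma: 0.01
  gamma: 1.3
  vignette: 0.2
  offset_rot: 5    # deg, unknown acquisition pose (registration recovers it)
  offset_trans: 5  # mm
augment3d:
  factor: 6
  rot: 10          # deg; desk-scale ranges keep the bones inside the FOV
  trans: 10        # mm
augment2d:
  factor: 16
  trans: 5
  rot: 8
  scale: [0.95, 1.05]
  shear: 4
xlate_patients: 12
translator:
  patch_radius: 3
  hidden: 64
  l1_weight: 100
  adv_weight: 1
  epochs: 10
  lr: 0.002
tlnet:
  latent: 64
  hidden: 48
  lambda1: 1.0e-4
  lambda2: 1.0e-4
  noise_sigma: 0.1
  iters: [700, 700, 350]
  lrs: [1.0e-4, 1.0e-4, 1.0e-5]
  batch: 12
split:
  folds: 4
  val_frac: 0.15
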