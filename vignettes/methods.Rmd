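---
title: "Single-view 2D-3D forearm bone reconstruction: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-view 2D-3D forearm bone reconstruction: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Estimating the 3D shape of the distal radius and ulna from a single
posteroanterior radiograph removes the radiation dose and cost of a CT scan
from workflows (surgical planning, kinematics, patient-matched instruments)
that today require a CT bone model. `xray2bone` implements a two-step
learning pipeline for this task:

1. **image translation** — a paired conditional adversarial network maps a
   degraded, bone-segmented radiograph to a clean segmented-bone DRR
   (digitally reconstructed radiograph), called the *GAN-DRR*;
2. **2D-3D reconstruction** — a TL-embedding network (a 3D label
   autoencoder `E`/`D` plus a 2D-to-latent predictor `P`) maps a DRR-like
   image to a per-voxel label volume {background, radius, ulna} via
   `argmax D(P(x))`.

The training data problem — paired radiograph/CT data are scarce — is
solved by rendering DRRs from (here: synthetic) CT volumes: an arbitrary
number of training images can be generated in arbitrary poses, and the
translation step brings real radiographs into the DRR domain at test time.

Because no clinical data ship with the package, every stage is exercised on
procedurally generated wrist phantoms with analytic ground truth. The
phantom generator is first-class, tested code: all acceptance benchmarks
run on it.

# The phantom family

A phantom is two elongated bones inside an elliptic soft-tissue cylinder:

* **radius analog** — a linearly tapered, capped cylinder along +Z (distal
  face at z = 0) with a half-ellipsoid *styloid* cap on the distal face,
  offset away from the ulna;
* **ulna analog** — a thinner cylinder whose distal face stops 2 mm short
  of the radius face, with a wider half-ellipsoid *head*; its azimuth about
  the radial axis is a free parameter emulating forearm-rotation
  variability;
* four analytic landmarks: the styloid tip, a notch point on the distal
  radius surface facing the ulna at zero rotation (the role of the volar
  sigmoid notch), two shaft-axis points, and the articular-surface center.

Bone solids have closed-form volumes (frustum + half-ellipsoid caps), used
as rasterization oracles. Hounsfield levels default to textbook values (air
-1000, soft tissue 40, trabecular 300, cortical 1200 HU) with a cortical
shell of configurable thickness. The population sampler draws every
geometric parameter uniformly from ranges loosely sized after adult
anatomy; draws are bitwise deterministic in the seed.

What the phantoms deliberately do **not** model: statistical shape
variation of real radii/ulnae, pathology, carpal bones and overlapping
anatomy, trabecular texture, scatter and beam hardening. Consequences of
these simplifications are flagged below where they matter.

# DRR rendering and its oracles

HU map affinely to linear attenuation, `mu = global_scale * max(0,
mu_water * (1 + HU/1000))`, clipped at zero (no negative attenuation).
`mu_water` defaults to 0.02/mm; `global_scale` (default 0.285) is
calibrated once so the reference phantom's segmented-bone DRR peaks near
0.20 optical depth — the intensity range the networks are trained on; the
same display range motivates reporting MAE in these units. Rendering is
fixed-step ray marching with trilinear sampling; the step must not exceed
the smallest voxel spacing (the renderer refuses rather than warns). The
default projection is orthographic along -Y, where the analytic oracles —
a slab integrating to `mu * t` and a sphere to the chord length
`2 mu sqrt(r^2 - d^2)` — are exact; a pinhole perspective mode exists but
is not the tested default. Rigid poses are rendered by tracing rays through
the inversely transformed volume, which is exact for rigid motion.

# Anatomical normalization

The anatomical frame follows the landmark construction: Z is the radial
shaft axis (pointing distal), the origin is the articular-surface point
projected onto that axis, X is the styloid-to-notch reference line
projected perpendicular to Z, Y completes the right-handed triad. Because X
is fixed on radial anatomy, the rotation of the radius about its axis is
unified across subjects while the ulna keeps its natural positional
variability — which is why the ulna reconstructs worse than the radius
here, as in clinical experience. Volumes are resampled onto a canonical
grid spanning exactly +/-40 mm along Z about the origin (trilinear for HU
with air padding, nearest-neighbour for labels with background padding), so
the estimation target is precisely the bone shape inside that field of
view.

The round-trip benchmark rasterizes a phantom at a random rigid pose
(+/-15 degrees, +/-8 mm), rebuilds the frame from the posed landmarks, and
compares the normalized label against the same phantom rasterized
analytically on the canonical grid; radius Dice exceeds 0.95 on all 20
seeds at 1 mm native / 1.25 mm canonical resolution. This isolates one
interpolation step; matching the two resolutions keeps nearest-neighbour
quantization from dominating.

# Augmentation and splitting

Two regimes mirror the two training sets:

* **3D rigid** (reconstruction training): uniform per-axis rotations and
  translations; the posed volume is re-projected (never a 2D warp of the
  DRR), and the target stays the unposed normalized label. The
  clinical-scale protocol uses +/-30 degrees / +/-30 mm and factor 40
  (173 volumes -> 6920 items); the desk preset uses +/-10 / +/-10 and
  factor 6, because at 32x32 detector resolution a +/-30 mm shift pushes
  most of a +/-40 mm field of view out of frame.
* **2D affine** (translation training): one sampled affine (translation,
  rotation, scale, shear) warps *both* members of a pair, preserving
  pairing; the clinical-scale factor is 100 (33 pairs -> 3300). Default
  ranges (+/-10 mm, +/-10 degrees, scale 0.9-1.1, shear +/-5 degrees) keep
  the bones in frame; the transform is recorded per item for auditability.

Cross-validation splits are patient-level: all augmented items from one
patient land on one side of every train/validation/test divide. The
85%/15% train/validation split is likewise made at patient level; an
item-level split of augmented data would leak near-duplicates of training
images into validation, so the stricter reading is used.

# 2D-3D registration

The similarity is gradient correlation: the mean Pearson correlation of
horizontal and vertical central-difference gradient images, invariant to
affine intensity rescaling and confined to [-1, 1]; constant images raise
an error rather than returning 0, because a silent zero would poison the
optimizer. The optimizer is a derivative-free coordinate-wise search with
step halving on a two-level image pyramid (documented capture range about
10 mm / 10 degrees); non-convergence returns the best pose found with
`converged = FALSE` rather than raising.

One geometric fact shapes the interface: under a single orthographic view,
translation along the ray is strictly unobservable, and for this
near-planar two-bone anatomy the two out-of-plane rotations are observable
only at second order (pilot runs reached similarity 0.999 with 7 degrees of
out-of-plane error). The default search therefore covers the observable
subspace — rotation about the ray axis plus detector-plane translations —
with `dof = "full"` available. The simulated acquisitions draw their
unknown pose offsets in the same subspace. On clean rendered targets the
recovery benchmark (offsets up to 5 mm / 5 degrees) succeeds within
1 mm / 1 degree; on degraded targets the error is about 1-2 mm — sub-pixel
at the desk detector's 2.5 mm pitch — which only blurs the translation
pairs slightly, exactly the role registration plays in the two-step design.

Registration, translation and the histogram baseline all consume the
*bone-segmented* radiograph: segmenting radius and ulna on the X-ray is the
first dataset-construction step of the method (the phantom pipeline uses
the projected true silhouette in place of manual segmentation). Without
segmentation, soft-tissue envelope gradients dominate the similarity and
registration fails — the same reason the protocol segments bones first.

# The image translator

A paired conditional adversarial translator in the pix2pix mold, at desk
scale: the generator is a dense network applied convolutionally to 7x7
patches plus three normalized position features (u, v, r^2). Position
awareness substitutes for the full-image receptive field of an
encoder-decoder generator; a patch-only generator cannot invert
position-dependent acquisition effects such as vignetting. The patch
discriminator scores (input patch, output patch) pairs; the objective is
`100 * L1 + 1 * adversarial` (reconstruction far above adversarial, the conventional weighting for
conditional-adversarial translation), optimized with Adam. Inputs and targets are
normalized to [0, 1] by dataset-level constants recorded in the state —
never per image — so absolute intensity information, which single-view
reconstruction depends on, survives translation. Setting the adversarial
weight to zero reduces training to supervised L1 regression, which is the
degenerate-objective test. Outputs are clipped at zero.

# The TL-embedding reconstruction network

Desk-scale architecture: two-layer ReLU dense networks for `E` (one-hot
label, V*3 inputs -> latent 64), `D` (latent -> V*3 logits) and `P` (DRR
pixels -> latent). The three training stages use Adam with the stage loss
functions

* stage 1 (denoising autoencoder, Gaussian noise sigma = 0.1 on the
  one-hot input):
  `L1 = L_label(D(E(y_noised)), y) + lambda1 * |E(y_noised)|_1`
* stage 2 (predictor, decoder frozen):
  `L2 = L_label(D(P(x)), y) + lambda1 * |P(x)|_1`
* stage 3 (predictor + decoder, encoder frozen):
  `L3 = L2 + lambda2 * |E(y) - E(D(P(x)))|_2`

with `L_label` the softmax cross entropy averaged over voxels and
`lambda1 = lambda2 = 1e-4`. Notes on readings that were genuinely open:

* the stage-1 objective combines its two terms as a sum, the same
  composition stages 2-3 use;
* the stage-3 consistency term compares `E(y)` with the re-encoded decoder
  output; the decoder's softmax probabilities are fed to `E` (a one-hot
  argmax would kill the gradient). A config switch
  (`latent_consistency = "predictor"`) offers the alternative reading that
  compares `E(y)` with `P(x)` directly;
* `|.|_1` is the sum of absolute latent entries and `|.|_2` the unsquared
  Euclidean norm, reading the subscripts in the loss definitions above
  literally; `norm = "l2sq"` switches to the squared form;
* cross entropy is averaged (not summed) over voxels so the lambda values
  are resolution-independent; the lambda = 1e-4 defaults are kept
  regardless.

Freezing is machine-checked: the frozen parameter set is verified bitwise
identical across its stage and the result is recorded in the returned
state. Training aborts with the stage and step named on any non-finite
loss.

# Scale: desk versus clinical protocol

Two presets ship. `paper.yaml` encodes the clinical-scale protocol —
400^3 volumes at 0.625 mm, 500x625 detector at 0.4 mm, FOV +/-40 mm,
augmentation factors 40 and 100 at +/-30 degrees / +/-30 mm,
35000/35000/15000 updates at learning rates 1e-4/1e-4/1e-5 — and is not a
tested path at desk scale. `desk.yaml` is the tested configuration, chosen
as the package's own working point for a single CPU: 56 phantoms on 48^3
native grids at 2.5 mm, canonical grid 24^3 over +/-40 mm (3.33 mm
voxels), 32^2 DRRs at 2.5 mm, hidden width 48, 700/700/350 updates with
batch 12, translator with 12 patients, 16x 2D augmentation and 10 epochs.
Learning rates, lambdas and the loss structure are identical in both
presets.

Desk-scale end-to-end accuracy varies noticeably across demo seeds (e.g.
mean radius ASD between about 1 and 2.6 mm; all four input conditions move
together), which is training-run variance of a 700-update-per-stage run,
not an input-pathway effect. The acceptance bound — held-out mean ASD below
2 canonical voxel spacings (6.67 mm) per bone — holds with margin across
the seeds examined.

# Evaluation

* **MAE** between two images is the mean absolute pixel difference in
  optical-depth units.
* **Surface point clouds** are the grid-edge iso-crossing vertices of the
  binarized class at iso level 0.5 — exactly the vertex set marching cubes
  interpolates on grid edges, without triangle topology, which a point-set
  distance never uses. Iso level and the vertex (rather than face-sampled)
  convention are package conventions; they are this package's
  conventions.
* **ASD** is the symmetrized mean nearest-neighbour distance between two
  point clouds. Nearest neighbours use a uniform-grid spatial index whose
  ring search is certified exact, and the test suite keeps an exhaustive
  double-loop oracle that must agree to 1e-9 — identical, not approximate.
* **The histogram-matched baseline** zeroes the image outside the bone
  mask and remaps within-mask intensities so their empirical CDF matches
  the registration-DRR template's (256-bin quantile mapping). Differences
  between conditions are reported descriptively as mean +/- s.d.;
  inferential testing is out of scope here.

The four-condition experiment feeds CT-DRR, GAN-DRR, registration-DRR and
the histogram-matched baseline through one trained reconstruction network
on the same held-out cases. On phantoms the expected ordering — CT-DRR best,
GAN-DRR no worse than the histogram baseline — reproduces, but the margin
between GAN-DRR and the baseline is small: a quantile remap with a per-case
registration-DRR template and an exact analytic segmentation is a far
stronger baseline on smooth soft-tissue phantoms than on clinical
radiographs, where unmodeled overlapping anatomy and texture degrade it.
Passing this ordering on phantoms therefore demonstrates pipeline
correctness, not the clinical effect size; the clinical accuracies
(radius about 1 mm) are not reproducible without the original patient data,
and this package makes no claim to them.

# Numerical and degenerate-input conventions

* Ray steps never exceed the smallest voxel spacing (error, not warning).
* Gradient correlation on constant images raises; registration catches the
  error at hopeless poses and treats the similarity as -Inf.
* The Euclidean-norm consistency gradient is guarded at ||e|| < 1e-8.
* Empty label classes make surface extraction raise; the experiment report
  records NA for a bone the reconstruction missed.
* All randomness flows through one RNG helper that seeds, draws and
  restores state, so every artifact is a pure function of (config, seed);
  sub-seeds derive deterministically from the global seed and stay below
  2^31.
* Degraded radiographs may carry slightly negative pixels (additive noise);
  rendered DRRs and translator outputs are non-negative by construction.

# Known limitations

* Dense desk-scale networks trade spatial inductive bias for CPU speed;
  convolutional architectures would be the choice at clinical resolution.
* The degradation model (soft-tissue weight, gamma, vignette, Gaussian
  noise) is a surrogate for unmodeled clinical variation, not calibrated to
  any scanner; its role is to give translation a nontrivial task.
* Out-of-plane pose components are not recovered by single-view
  registration here; biplanar acquisition would be required.
* Phantom anatomy is schematic; landmark correspondence to the clinical
  definition (styloid process, volar sigmoid notch) is by role, not by
  anatomy.
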