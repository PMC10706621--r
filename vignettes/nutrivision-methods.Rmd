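---
title: "Estimating dish nutrition from images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating dish nutrition from images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Estimating the nutritional content of a meal — calories (kCal), mass, fat,
carbohydrate and protein (g) — from a single top-down photograph is
ill-posed: the projection to a monocular image discards the 3D structure
that determines portion size. `nutrivision` follows the two-stage remedy:
first predict a dense depth map from the RGB image with a transformer-based
monocular depth model, then fuse the RGB and (predicted or sensor) depth
streams in a two-stream convolutional network whose cross-modal attention
block (CAB) and multi-scale fusion cascade produce the features for five
regression heads.

Everything in the package runs at desk scale on a single CPU: the models
are configurable down to a few thousand parameters, training is driven by a
compact reverse-mode automatic-differentiation engine written for this
package, and a synthetic dish-scene generator supplies (RGB, depth,
nutrition) triplets with analytically exact ground truth.

## The synthetic scene generator

A scene is a plate on a table viewed from a camera at height `camera_height`
(default 35 cm — a typical overhead capture rig). Ingredients are elliptical
blobs with a parametric height profile (paraboloid cap
`h(x, y) = h_max * (1 - r^2)` or cylinder), a class drawn from an ingredient
table (density g/cm^3, kCal/g, macronutrient mass fractions, RGB albedo),
and footprints on the flat interior of the plate. Overlapping blobs are
resolved by the maximum height — stacked food occludes what is beneath it,
which deliberately reproduces the stacking failure mode of real dishes; the
generator's `overlap` flag produces such scenes on demand.

Ground truth is exact: with pixel area `a` (cm^2, derived from a 30 cm
physical width across the short image side),

* `mass_c = sum_pixels h(x, y) * a * density_c` per visible class `c`,
* `calories = sum_c mass_c * kcal_per_g_c`, macros via mass fractions,
* `depth = camera_height - surface_height` (cm; closer is smaller).

RGB is the per-pixel class albedo under top-down Lambertian shading
(brightness proportional to the cosine of the surface slope) plus optional
Gaussian noise (sd 0.01); depth receives optional sensor noise (sd 0.15 cm,
a few millimetres, as for a consumer depth camera). The shading gives RGB a
*weak* height cue — slope, not absolute height — so depth carries genuinely
complementary information about volume, while RGB alone carries the class
(hence energy-density) information. This asymmetry is what makes the
ablation ordering achievable but not trivial: a depth-only model cannot
recover the ingredient composition, an RGB-only model can only coarsely
infer volume.

What the generator does *not* emulate: photorealistic texture, specular
highlights, cast shadows, ingredient-level segmentation boundaries,
occlusion by cutlery, or the label noise of real nutrition databases.
Passing tests on synthetic data therefore demonstrate that the
architecture, losses and training loop are correct and that depth
information is exploited — not that the package reaches any particular
accuracy on real dishes.

Depth maps are written as 16-bit TIFF with the cm-per-unit scale declared
in a YAML sidecar (`scene_meta.yaml`); at 35 cm camera height the
quantization step is ~5e-4 cm, far below sensor noise. RGB is 8-bit PNG.

## The depth prediction module

A convolutional patch embedder (stride-2 conv stack with total stride
`p = 16`) abstracts the image into `Np = H*W/p^2` tokens of dimension `D`,
adds a trainable position embedding and an optional readout token, and runs
them through `n_blocks` pre-norm transformer blocks
(`t <- t + MSA(LN(t))`, `t <- t + MLP(LN(t))`). Token count and dimension
are constant across the encoder — there is no progressive downsampling, so
all stages keep a global receptive field. Four tapped stages are
reassembled into image-like maps (tokens placed at their raster grid
positions, 1x1-projected to the decoder width, then resampled by factors 4,
2, 1, 1/2), and a RefineNet-style decoder fuses them coarse-to-fine (x2
upsampling plus residual conv units) into a full-resolution depth map.

Numerical choices:

* **Output head**: `depth = depth_scale * softplus(z)` — depth in cm is
  physically non-negative. The final conv is initialized with small weights
  and a bias placing the initial prediction near 85% of `depth_scale`
  (a typical plate distance), a calibrated-init convention that starts
  optimization from a plausible constant rather than from zero.
* **Readout token** is discarded at reassembly (the simplest consistent
  treatment).
* **Training loss**: masked mean absolute error in cm. The synthetic depth
  is metric, which makes plain L1 well-posed; a scale-and-shift-invariant
  variant (align prediction to ground truth by least squares, then L1) is
  available via `loss = "ssi"` for relative-depth settings.
* Desk-scale default: 64x64 input, `p = 16` (16 tokens), `D = 64`, 4
  blocks, 4 heads, decoder width 32. The full-scale profile
  (`inst/configs/depth_full.yaml`) uses 384px inputs and ViT-Base
  dimensions and is not exercised by the tests.

Because a flat plate at a roughly known camera distance dominates the
scene, AbsRel on these scenes is low even for a near-constant prediction;
the sharper trainability check is that the training loss strictly decreases
from its starting value, which the test suite asserts separately.

## The RGB-D fusion module

Twin five-stage backbones (stride-2 conv + channel-affine normalization +
ReLU per stage) extract feature pyramids `{R_i}` and `{D_i}`, strides 2 to
32. The depth map is normalized by a **fixed** scale (the camera height)
and replicated to three channels before its stem. A per-image min-max
normalization is available (`depth_norm = "minmax"`) but is not the
default: min-max discards the absolute metric scale, which is precisely the
volume information the depth stream is meant to contribute.

At each level the CAB computes shared attention from the additive features:

* channel attention `CA = Sig(ReLU(Norm(Conv1x1(GAP(R + D)))))`, one value
  per channel in (0, 1);
* spatial attention `SA = Sig(ReLU(Norm(Conv3x3(Mean_c(R + D)))))`, one
  value per pixel in (0, 1);
* fused features `C_i = Conv1x1(Concat(R*CA*SA, D*CA*SA))`, back to the
  level's channel count.

Both modalities are gated by the *same* CA and SA (fuse-enhance-fuse): the
attention is computed from the cross-modal sum and used to re-calibrate
each stream before the final concatenation. Setting CA and SA to one
everywhere reduces the block exactly to concatenation + 1x1 convolution,
the direct-fusion baseline; the test suite asserts this equivalence as an
exact tensor identity under shared weights.

The multi-scale cascade is `F_0 = C_0`, `F_i = C_i + Res_i(F_{i-1})`, where
`Res_i` is a stride-2 bottleneck residual block with a projection shortcut.
The progressive form (feeding `F_{i-1}`) follows the prose description of
repeated fusion; the literal variant `F_i = C_i + Res_i(C_{i-1})` is
available behind `literal_cascade = TRUE`. The final `F_4` goes through
global average pooling, one shared FC layer and five single-output heads
(`shared_head = FALSE` builds five fully separate stacks instead).
Normalization layers are channel-affine transforms operating with fixed
statistics, so every unit-test example is deterministic.

## Losses, metrics and training

Per task the loss is the batch mean absolute error; the combined loss is
the **geometric mean** of the five task losses, computed in log space. The
geometric mean is invariant to per-task scale, so kCal-sized and gram-sized
errors are balanced without hand-tuned weights.

Two training-specific choices deserve explanation:

* **Target normalization.** Targets are divided by their training-split
  means (stored in the model as `y_scale`, predictions are mapped back to
  original units), and each head's bias starts at 1 so the initial
  prediction is the training mean. This conditions the optimization
  without affecting the reported metrics.
* **Loss floor.** The gradient of the geometric mean w.r.t. task `k` is
  proportional to `L / L_k`: as a task's loss approaches zero its factor
  diverges, and in an overfitting regime the sign-noise of already-solved
  tasks drowns the gradient of the still-unsolved ones. The trainer
  therefore clamps task losses below `loss_floor` (default 1e-2 in
  normalized units, i.e. 1% of the task mean) and cuts their gradient: a
  task below the floor is treated as solved. The exported
  `geometric_loss()` metric keeps a purely numerical guard (1e-8) instead,
  since as a measurement it should not be floored.

Training is two-stage: the depth model first (Adam, cosine-annealed lr),
then the fusion model (Adam, exponential per-epoch lr decay) with the depth
module frozen when it supplies the depth input — the test suite asserts the
depth parameters are bit-identical before and after fusion training.
Augmentations are applied to the RGB image and depth map of a dish
together, never independently: horizontal flips, and for square top-down
scenes the full dihedral group (flips plus 90-degree rotations), which are
label-preserving because an overhead dish scene has no preferred
orientation. Desk-scale recipes use Adam at 2e-3 to 5e-3 — conventional
rates for networks of this size — with constant lr (`lr_decay = 1`) for
full-batch overfitting runs, where an "epoch" is a single step and
per-epoch decay would freeze the optimizer prematurely. The full-scale
reference recipes (1e-5 cosine for depth; 5e-5, decay 0.98 for fusion;
150/60 epochs; batch 8) ship as `inst/configs/*_full.yaml`.

Evaluation reports MAE and PMAE (MAE divided by the mean ground truth, in
percent) per nutrient plus their mean, and for depth AbsRel, RMSE and the
threshold accuracies delta < 1.25, 1.25^2, 1.25^3 (strict inequality;
pixels exactly at a threshold do not count). In the AbsRel definition the
denominator is the ground-truth depth; metrics are computed dataset-level
over all test dishes.

## The ablation harness

`run_ablation()` mirrors the architecture ablation at desk scale: variants
(a) RGB-only, (b) depth-only, (c) direct fusion, (d) + multi-scale cascade,
(e) + CAB are trained per seed on a synthetic set (default 200 train / 50
test dishes, 32x32 px, three seeds) and compared by test mean PMAE. The
expected qualitative ordering is that (b) is worst — depth carries no
ingredient identity, so energy density is unrecoverable — and (e) performs
at least as well as (a) in the majority of seeds, because depth contributes
the volume information RGB lacks. The harness trains on sensor (generator)
depth by default to decouple the fusion question from depth-model quality;
`depth_source = "predicted"` runs the full monocular pipeline. Problem
sizes for the shipped desk recipes (1000 steps, batch 8, lr 5e-3, backbone
channels 4-64, dihedral augmentation, one shared dish set across training
seeds) were chosen as the smallest configuration at which the variants
separate cleanly from mean-prediction behaviour and approach their
information floors on this task; at this scale the variants remain
underfit in absolute terms, so only the qualitative ordering — not the
absolute PMAE — is meaningful. Two training-dynamics effects matter at
this scale and are worth knowing about: without augmentation the
single-stream models overfit the 200 training dishes (test error rises
with further training), and the fused model needs more steps than the
single-stream ones before its RGB pathway contributes to the
composition-dependent tasks, because the geometric loss's `1/L_k`
weighting deprioritizes the worst task while depth offers quick wins on
mass and calories.

## Known limitations

* Single-sample processing: the engine differentiates one dish at a time
  and accumulates gradients over the batch, trading throughput for
  simplicity; desk-scale configurations keep runs in minutes.
* The synthetic task's difficulty is not calibrated to Nutrition5k;
  absolute PMAE values here are not comparable to published benchmarks.
* The affine normalization layers do not track batch statistics, so very
  deep full-scale configurations may need care with initialization.
* `"ssi"` depth training treats the per-batch alignment coefficients as
  constants in the backward pass.
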