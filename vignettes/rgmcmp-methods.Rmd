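---
title: "Registration-guided multi-channel multi-path CTV segmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Registration-guided multi-channel multi-path CTV segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In adaptive radiotherapy (ART) a patient is re-imaged and re-planned
during treatment. The clinical target volume (CTV) must be re-contoured
on every new planning CT — slow when done by hand, and unusually hard
for automatic methods because CTVs are defined partly by rules (margins
for suspected microscopic spread) rather than by visible intensity
boundaries. Two families of automation exist, each with a
characteristic failure mode:

* **Contour propagation via registration.** Rigid-body (RB) or
  deformable (DIR) registration aligns the first-course CT (CT1) to the
  second-course CT (CT2), and the first-course contour (CTV1) rides
  along. This uses patient-specific prior information but inherits
  every registration error, and cannot model CTV changes that are not
  intensity-driven (e.g. tumor regression combined with a fixed
  margin rule).
* **Direct deep-learning segmentation.** A network trained on many
  patients segments CT2 alone. It can learn margin rules, but with low
  soft-tissue contrast it lacks the patient-specific information that
  the earlier course provides.

`rgmcmp` implements the combination: contours are first propagated by
registration, then the aligned image (aCT1), aligned contour (aCTV1)
and CT2 are fed as three channels to a 3D encoder–decoder network that
refines the propagated contour — the registration-guided multi-channel
multi-path (Rg-MCMP) framework. Every input channel gets its own
encoder path; features are only merged in the decoder.

## The pipeline

```{r}
library(rgmcmp)

# one seed of the frozen desk-scale comparison (cohort generation,
# registration, preprocessing, training, evaluation, statistics)
oe <- ordering_experiment(seeds = 1)
oe$mean_dsc
```

`ordering_experiment()` is a thin wrapper that fixes the cohort,
preprocessing, and training configurations and calls
`run_experiment()`; use `run_experiment()` directly for custom
cohorts, method subsets, or configurations.

The stages, and the modelling choices inside each, are described below.

## Synthetic paired-course phantom

Clinical paired-course datasets are private, so the package ships a
generator whose cases have the same *structure*: per case a course-1
volume + CTV and a course-2 volume + CTV, related by an unknown smooth
deformation plus a rigid offset, with CT-like intensities and noise.
The scene is analytic; course 2 is rendered by evaluating the scene at
warped coordinates, so the ground-truth inter-course transform is exact
rather than a raster warp, and it is stored with each case as a dense
deformation vector field.

What the phantom emulates, and why each ingredient is there:

* **Elliptical body cylinder** (~0 HU on −1000 HU air, lateral
  semi-axes ratio 1.15 : 0.8 like a pelvic cross-section) — gives the
  registration gradient structure; the azimuthal asymmetry makes
  rotations observable to an intensity metric.
* **Two bone rods** (+700 HU) — high-contrast landmarks, as hip bones
  are in practice.
* **A visible lesion** (+60 HU over body at course 1) whose CTV is the
  lesion plus a *fixed* 10 mm margin. Between courses the lesion
  regresses or grows (semi-axes scaled by a per-case factor drawn
  from U(0.7, 1.3)) while the margin rule stays fixed — exactly the
  component of CTV change that intensity-driven registration
  propagates incorrectly (it scales the margin along with the lesion)
  but that a trained network can learn.
* **Course-2 contrast fade** (lesion contrast multiplied by 0.75) —
  post-treatment changes reduce tumor conspicuity, so CT2 alone
  under-determines the boundary.
* **A decoy organ** with the lesion's contrast on the mirrored side of
  the body, with the lesion side randomized per case — CT2 alone
  cannot tell target from decoy, so the prior-course contour carries
  genuine patient-specific information. This reproduces, in miniature,
  why guidance matters clinically.
* **Rigid offset + smooth warp**: per-case translations up to ±6 mm,
  small rotations, and a smooth random warp (cubic B-spline lattice,
  40 mm correlation length, amplitude capped at 8 mm < half the
  correlation length so the map stays invertible), plus independent
  Gaussian intensity noise (20 HU) per course.

Defaults were chosen once so that the qualitative method ordering of
the comparison experiment is observable at desk scale; they are not
calibrated to clinical deformation statistics, and the phantom has no
bladder/rectum filling models or CBCT artifacts. Consequences for
interpretation: passing tests show the pipeline orders methods
correctly when guidance carries real information and registration
faces rule-based contour changes — they do not certify clinical
accuracy levels.

Seed policy: a cohort seed derives per-case seeds by a counter scheme;
every case records its seed, and regenerating with the same seeds is
bit-identical.

## Registration

**Rigid stage.** 6-DOF transform (rotations about the volume centre +
translation), Mattes mutual information with 32 linearly binned
histogram levels, optimized by regular-step gradient descent (initial
step 8, step halved when a trial step fails to improve the metric,
termination at step < 0.001 or the iteration budget) over a four-level
multiresolution pyramid. Two numerical choices matter on
piecewise-constant images and are worth stating:

* Metric samples are taken at *sub-voxel-jittered* positions (a fixed,
  deterministic jitter), so the fixed image is interpolated exactly
  like the moving one. On-grid sampling makes MI *increase* under
  slight misalignment (interpolation mixing raises the marginal
  entropy without raising the joint), which biases the optimum.
* Both images are smoothed with a one-voxel box kernel at every
  pyramid level. Without it MI develops spurious maxima wherever the
  translation is an exact integer number of voxels (the interpolation
  patterns of the two grids lock).

**Deformable stage.** A cubic B-spline free-form deformation with
control-point spacing of 16 voxels at the finest level, optimized over
the same four-level pyramid, initialized by the rigid stage. The
similarity metric is the mean squared intensity difference with its
analytic gradient (residual × moving-image gradient, pulled back to
the control lattice through the exact B-spline adjoint): for same-
modality CT-to-CT pairs SSD is well matched, and the analytic gradient
makes a dense control lattice tractable, which a histogram metric would
not be. Two robustness guards: optimization stops when the SSD falls
below 1e-6 of the fixed-image variance (below that the residual is
interpolation noise, and chasing it produces spurious warps on
noise-free images), and a step is only accepted if it improves the
loss by at least a 1e-4 relative margin. The composite map
(rigid ∘ B-spline) is materialized as a dense voxelized DVF on the
fixed grid, whatever the internal parameterization.

Propagation resamples images with trilinear interpolation (out-of-field
voxels filled with −1000 HU) and masks with nearest-neighbour (filled
with 0), so masks stay strictly binary.

## Preprocessing

The chain mirrors the clinical recipe: extract a 48-slice axial slab
containing the whole CTV (centred on the mask's axial midpoint when
there is slack, clamped to the volume); crop laterally to the bounding
box of the union of the body contours of CT2 and the aligned CT1 (body
contour: threshold at −300 HU, largest 3D connected component,
one-voxel closing, hole fill — the construction is the package's
choice, as is the slab→crop→resample order); resample to a fixed
training grid (192 × 160 × 48 by default; linear for images, nearest
neighbour for labels); truncate to (−1000, 1500) HU and map affinely
to (0, 1). Normalization treats input already inside [0, 1] as
normalized, which makes the chain idempotent.

## Network family

One factory builds all four architectures of the comparison:

| variant | input | encoder paths | extras |
|---|---|---|---|
| `unet3d` | CT2 | 1 | isotropic downsampling, no attention, no deep supervision |
| `scsp` | CT2 | 1 | anisotropic schedule + channel attention + deep supervision |
| `mcsp` | aCT1, aCTV1, CT2 stacked | 1 | same decoder as mcmp |
| `mcmp` | aCT1, aCTV1, CT2 | 3 (one per channel) | same decoder as mcsp |

Common structure: every conv module is a 3×3×3 convolution + instance
normalization + LReLU (α = 0.2); each resolution level has two conv
modules; downsampling is a stride-2 convolution that doubles the
channel count; the first and last downsampling steps leave the axial
dimension unchanged (input slabs are much thinner than they are wide:
192 × 160 × 48 → axial sizes 48, 48, 24, 12, 12); the decoder
upsamples with transposed convolutions (kernel = stride) and receives,
at each depth, skip connections from *every* encoder path. Multi-path
means exactly that: the three paths share no parameters and exchange
no features before the decoder; the audit in `model_audit()` verifies
the encoder parameter count of `mcmp` is exactly three times that of
`scsp`.

Choices on points the architecture family leaves open:

* **Classes**: K = 2 (background, CTV) with a softmax over classes, so
  the class-indexed loss sums read literally.
* **Channel attention placement**: a squeeze-excitation gate (global
  average pool → reduction bottleneck, ratio 8 by default → sigmoid)
  applied to the *concatenated multi-path skip tensor* at each decoder
  depth — that is where re-weighting channels across paths is
  meaningful. The excitation weights start at zero, so gates start
  neutral at 0.5 and the re-weighting is learned.
* **Deep supervision**: 1×1×1 heads at the three coarsest decoder
  levels; their logits are upsampled trilinearly to full resolution,
  summed with the final head, and softmaxed; the loss sees only the
  combined map (no per-head auxiliary terms).
* **Depth and width**: five levels / four downsamplings with 16 base
  filters by default, configurable downward (the shipped tests and
  experiments use three levels / 4 filters).

The whole engine (convolutions via im2col + GEMM, transposed
convolutions, instance norm, attention, upsampling adjoints,
backpropagation, Adam) is implemented inside the package in R and
C++; the backward pass is verified against central finite differences
through the full architecture in the test suite.

## Objective and training protocol

The loss is the equal-weight sum of voxel-averaged cross-entropy and
soft Dice, `L = 0.5 Lce + 0.5 Ldice`, with the Dice smoothing constant
ε = 1 (a class empty in both prediction and truth contributes a
perfect ratio) and probabilities clipped at 1e-7 inside the logarithm
so the cross-entropy stays finite.

Training: he_normal initialization from a seed, Adam, batch size 1,
initial learning rate 2e-4, validation loss once per epoch; after 30
consecutive epochs without a new best validation loss the rate is
multiplied by 0.2 (repeatably — the counter restarts from the drop);
after 50 the run stops; the returned model is the parameters at the
minimum validation loss. "Did not decrease" means strict improvement
of the best-so-far value with zero tolerance. Data order is reshuffled
each epoch from the run seed and there is no augmentation. The same
configuration object drives every variant in a comparison, so
performance differences are architectural.

## Metrics

DSC (`2|A∩B|/(|A|+|B|)`, two empty masks defined as 1), HD95, and ASD.
Surface voxels are mask voxels with a face-adjacent background
neighbour (the grid boundary counts as background); distances are
Euclidean in physical millimetres between voxel centres, computed with
an exact anisotropic distance transform and checked against an
all-pairs oracle in the tests. HD95 is the 95th percentile of the
pooled symmetric surface-distance multiset with linear interpolation
between order statistics; ASD is the mean of the same pooled multiset
(the symmetric reading of "average surface distance"). Both directions
are always pooled, so all three metrics are symmetric in their
arguments.

## The comparison harness

`run_experiment()` splits a cohort into train/validation/test
partitions in 4:1:1 proportions (mirroring a 60/15/15 design), prepares
each case once per guidance mode (none / rb / dir), trains each
deep-learning method with the shared protocol, and scores every method
on the identical test partition. Statistics: two-sided paired t-tests
on per-case DSC (directional claims are reported alongside, but the
test itself is two-sided — conservative and unambiguous), no
multiple-testing correction (flagged in the printout), and the Pearson
correlation R between ΔRegistration (per-case DSC of DIR minus RB) and
ΔRg-MCMP (per-case DSC of DIR-MCMP minus RB-MCMP).

## The desk-scale ordering experiment

`ordering_experiment()` freezes a configuration on which the
qualitative structure of the clinical comparison is measurable in
minutes on one CPU: three seeds, each with its own 18-case cohort
(12 train / 3 validation / 3 test) on a 48 × 48 × 28 phantom grid at
3 mm, preprocessing to a 40 × 40 × 16 training grid (the margin-rule
signal is about one voxel at coarser lateral resolution, so the
comparison needs this much detail), networks with 4 base filters and
3 levels, learning rate 1e-2 with patience 10/20 and at most 70
epochs (early stopping normally fires near epoch 30) — a desk-scale
protocol applied identically to every variant. Pooled across seeds it reproduces the orderings: deformable
propagation ≥ rigid, guided models ≥ the unguided single-channel
model (by a wide margin, because of the decoy ambiguity), multi-path ≥
single-path, and the guided multi-path model ≥ standalone deformable
registration. Absolute clinical DSC levels are out of reach at this
scale and are not asserted.

## Known limitations

* The phantom's anatomy is schematic; its difficulty dials
  (decoy, fade, margin) are designed to make method differences
  observable, not to match clinical effect sizes.
* The B-spline stage is SSD-based and mono-modal; multi-modal pairs
  would need a histogram metric with an analytic gradient.
* The conv engine is CPU-only and sized for small grids; the default
  five-level / 16-filter architecture is buildable and auditable, but
  training it at full grid size is not a desk-scale operation.
* Registration reports no inverse-consistency or Jacobian diagnostics.
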