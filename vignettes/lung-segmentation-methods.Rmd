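---
title: "Segmenting normal lung excluding the trachea and main bronchi: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting normal lung excluding the trachea and main bronchi: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungseg)
```

## The problem

Radiotherapy planning for lung cancer needs the *normal lung* delineated on
CT — and by the organ-at-risk convention the trachea and main bronchi are
not part of it. Dose constraints such as V20 and mean lung dose are computed
over this structure, so a segmentation tool that bleeds into the central
airway (a typical failure of atlas-based tools at the hilum) systematically
misstates them. `lungseg` implements an end-to-end pipeline for this task:
DICOM CT and RT Structure Set ingestion, rasterization to binary masks, 2D
and 3D U-Net segmentation networks trained with a composite overlap loss,
flip/inversion augmentation, 5-fold cross-validation with per-voxel
majority-vote ensembling, and Dice-based cohort comparison with the
Wilcoxon signed-rank test.

Everything is testable without clinical data: a synthetic thorax phantom
generator supplies volumes whose ground truth has the defining property of
the target structure — two lung-like components with a central airway that
must be *excluded*.

## Metrics and the loss

For a reference voxel set $A$ and an estimate $B$,

$$\mathrm{IoU}(A,B) = \frac{|A\cap B|}{|A\cup B|}, \qquad
  \mathrm{DSC}(A,B) = \frac{2|A\cap B|}{|A|+|B|}, \qquad
  \mathrm{Loss} = 2 - \{\mathrm{IoU} + \mathrm{DSC}\}.$$

`overlap()` computes the hard versions by exact voxel counting; the
algebraic identity $\mathrm{DSC} = 2\,\mathrm{IoU}/(1+\mathrm{IoU})$ holds
to machine precision and is asserted in the tests. Two conventions had to
be fixed where set notation is silent:

* **Both masks empty** → DSC = IoU = 1, loss = 0. Degenerate slices agree
  perfectly; any other convention poisons cohort means.
* **Soft relaxation.** Training needs gradients, so `soft_loss()` replaces
  counts with sums over the probability map ($I=\sum p g$, $|B|=\sum p$) and
  adds $\varepsilon = 10^{-6}$ to every numerator and denominator. The form
  $(x+\varepsilon)/(y+\varepsilon)$ makes the loss exactly 0 at $p = g$,
  including for empty masks, and it reduces to the hard loss on binary $p$
  as $\varepsilon \to 0$.

A related choice concerns *reporting* the training soft-DSC. Phantom (and
thoracic CT) stacks contain slices with no lung at all; with
$\varepsilon = 10^{-6}$ a per-slice soft-DSC of an empty slice is ~0 even
when the prediction is essentially perfect, capping a per-slice mean near
0.7 regardless of quality. The package therefore pools the soft counts over
the evaluated set before forming the ratio — the same convention used for
per-case hard DSC, where a case is scored as one voxel set rather than as a
mean over its slices.

## The networks

Both networks are fully authored in the package (im2col-based convolutions
with BLAS matrix products, hand-derived backward passes, Adam), since the
composite-loss U-Net is the method under study. Architectures are built
from declarative specs:

* **2D U-Net** (`unet2d_spec()`): 128×128 single-channel slices; 2×2
  shape-preserving convolutions (even kernels take the extra zero pad on
  the high-index side); two conv–batch-norm–ReLU blocks per level; 2×2 max
  pooling, three times, to a 16×16 bottleneck; dropout (rate 0.5) at the
  bottleneck; 2×2 stride-2 transposed-convolution upsampling with skip
  concatenation; a 1×1 sigmoid head.
* **3D U-Net** (`unet3d_spec()`): 32×128×128 volumes; kernels drawn from
  the menu {1×3×3, 2×3×3, 1×1×1}; an anisotropic pooling schedule with
  default (1,2,2), (1,2,2), (2,2,2), (2,2,2), which pools z in exactly two
  stages and reaches the 8×8×8 bottleneck; nearest-neighbour upsampling
  mirroring each stage's pooling factors; channel counts capped at 772.

Design points that were genuinely open and how they were fixed:

* **Per-level channel schedules.** Only the depth and the 3D maximum (772)
  are pinned by the architecture description; defaults double per level
  (2D: 64→128→256, bottleneck 512; 3D: 48, 97, 193, 386, 772) and are
  fully configurable. Tests and the acceptance runs use tiny schedules —
  the contracts (shape preservation, bottleneck size, output range) are
  schedule-independent.
* **Dropout placement**: bottleneck only, the standard reading of "a
  portion of the units are randomly deactivated" when no site is given.
* **Batch normalization**: after each convolution, before the activation;
  inference uses running statistics with momentum-0.1 updates.
* **Kernel placement (3D)**: 1×3×3 at the two shallowest levels (where the
  z extent is still large relative to pooling), 2×3×3 deeper; the 1×1×1
  menu member is available per level and used by the output head.
* **Transposed-convolution outputs** are left linear (no normalization or
  activation) — the following two conv blocks normalize the concatenated
  tensor; this keeps the skip branch and the upsampled branch symmetric.
* The sigmoid input is clamped to ±30 so outputs are strictly inside
  (0, 1) in double precision.

## Training

`train_fold()` minimizes the mean per-slice (2D) or per-volume (3D) soft
loss with Adam. Choices:

* **Augmentation ×4**: original, left-right flip, intensity inversion
  ($v \mapsto 255 - v$), and both. The flip is applied to image *and* mask;
  the inversion to the image only — a mask is a label image, and inverting
  it would corrupt the supervision rather than augment the input
  distribution.
* **Learning-rate grid**: 0.3, 0.1, 0.03, 0.01, 0.003, 0.001, 0.0003,
  0.0001 (`lr_search()` picks the grid member with the lowest final
  validation loss, ties to the smaller rate).
* **Gradient clipping** (global L2 norm, default 1): overlap losses
  produce occasional large gradient spikes once predictions are nearly
  perfect (the denominators shrink with the symmetric difference), and with
  batch normalization a single oversized Adam step can knock a converged
  model off its optimum for tens of epochs. Clipping bounds the step
  without changing its direction. Set `grad_clip = Inf` to disable.
* **Fold models keep their final-epoch weights** — no early stopping,
  matching a fixed-epoch-budget protocol.
* Batch sizes default to 8 slices (2D) / 1 volume (3D) and are
  configurable.

`ensemble_vote()` combines the five fold models per voxel: foreground iff
strictly more than half the models vote 1 (with five models a 3-vs-2 vote
elects the majority; the tie rule for even counts defaults to background).
Voting operates on binarized maps (threshold 0.5), not averaged
probabilities — the vote of discrete inferences is the construction being
studied.

## The phantom generator

`generate_phantom()` emulates the *geometry* of the segmentation problem,
not CT physics:

* two lung ellipsoids inside a soft-tissue body ellipsoid on an empty
  background, with distinct grey levels (defaults 64, 120, 0) in an 8-bit
  range — the pipeline consumes PNG-converted intensities, not Hounsfield
  units;
* a bright airway tube (default grey 200) descending from the top of the
  volume and bifurcating into two oblique branches that enter the lungs;
  the ground-truth mask is *lungs minus airway*, so a learner (or a
  degraded comparator) that includes the tube is measurably wrong;
* additive Gaussian noise (sd 6 by default), clipped to [0, 255];
* all geometric defaults are fractions of the grid, so a 16×32×32 phantom
  for fast experiments and the full 32×128×128 geometry share their
  relative anatomy. The default lung z-semiaxis fraction (0.34) leaves
  headroom so jittered cohorts always fit the grid.

`generate_cohort()` scales semiaxes by U(0.85, 1.15) and displaces centres
by U(−0.15, 0.15) of the corresponding semiaxis. Displacing by a fraction
of the *semiaxis* (rather than of the centre coordinate) keeps every
jittered case inside the grid by construction; per-case noise seeds derive
deterministically from the cohort seed.

What passing on phantoms does **not** show: robustness to real CT texture,
pathology (tumours abutting the airway), scanner variation, or contouring
ambiguity at the hila. The phantom isolates the structural question — can
the pipeline learn to exclude a tubular structure from an otherwise
homogeneous target — and verifies the machinery end to end.

## Geometry normalization and I/O

DICOM CT series are sorted by patient z with rescale slope/intercept
applied; RT Structure Set contours are filled per slice by the even–odd
rule evaluated at pixel centres (points exactly on an edge count as
inside), multiple contours of one structure combine by parity so inner
contours carve holes, and requested structures merge by union (e.g. right
lung ∪ left lung, optionally minus an airway structure via
`boolean_combine()`).

`normalize_case()` maps any stack to the fixed 32×128×128 network
geometry: area averaging in-plane for intensities (bilinear when the size
ratio is not integer), nearest neighbour for masks so labels stay binary;
slice counts are forced to 32 by uniform index sampling
(`round(i * (Z-1)/31)`) when longer — preserving the full cranio-caudal
extent, which a lung target requires — and by symmetric zero padding when
shorter. Intensities are windowed linearly to [0, 255], by default over the
per-case min–max range; the window is recorded in the case metadata.
PNG stacks are lossless 8-bit; mask PNGs must be strictly {0, 255} and any
other value is rejected on read.

## Statistical comparison

`summarize_dsc()` reports mean ± sample SD, a Student-t 95% confidence
interval ($m \pm t_{0.975,\,n-1}\, s/\sqrt{n}$ — at n = 32 the normal and t
intervals differ negligibly, and the t choice is recorded here), maximum,
median and minimum. `wilcoxon_signed_rank()` drops zero differences,
assigns mean ranks to ties, enumerates all $2^n$ sign assignments for
n ≤ 12 (a two-sided p from the permutation distribution of the positive
rank sum, valid under ties), and otherwise uses the normal approximation
with tie correction and, by default, continuity correction — both variants
of the asymptotic path are exposed because GUI statistics front-ends for R
apply the correction by default. `compare_techniques()` assembles the
two-technique report with the paired p-value and a significance flag at
0.05; identical score lists are reported as "no difference" rather than an
error.

## Problem sizes used by the tests and the acceptance script

The shipped verification runs on one CPU and chooses sizes accordingly —
these are the package's study conditions, fixed once:

* metric and voting oracles: 1000 and 200 random mask sets;
* architecture contracts: full-size 128×128 and 32×128×128 inputs with
  tiny channel schedules (4–16 channels), since the spatial contracts are
  channel-independent;
* capacity check: two 16×32×32 phantoms, a 32×32-input 2D spec with
  channels 8/16/32, learning rate 0.01 (the best grid member at this scale
  in a small search), batch 16, 150 epochs — the trained network must reach
  soft-DSC ≥ 0.95 on its training cases;
* end-to-end experiment: 25 phantoms (20 for 5-fold cross-validation, 5
  held out), 5 epochs per fold, majority-vote ensemble scored against
  ground truth and against a deliberately degraded baseline (truth dilated
  by 2 voxels, which swallows the airway — the failure mode of the atlas
  comparator this pipeline is designed to beat). With five held-out cases
  the exact two-sided signed-rank p cannot go below $2/2^5 = 0.0625$;
  the report carries it alongside the effect size, and the experiment's
  claim rests on the DSC gap.

## Known limitations

* The networks run on CPU in plain R/C++; they are faithful and tested but
  not fast — full-size, full-channel training is out of reach here and was
  never the goal of the package.
* Phantoms do not model CT physics, tumours or contouring variability (see
  above).
* DICOM support covers explicit/implicit VR little endian, axial
  identity-orientation geometry, and uncompressed pixel data — the subset
  the pipeline needs; there is no DICOM writing.
* The 3D default channel schedule honours the 772-channel cap as a cap;
  nothing in the package depends on that particular number beyond the
  validation.
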