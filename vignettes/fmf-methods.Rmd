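---
title: "Automated FMF-angle measurement: models, phantoms and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated FMF-angle measurement: models, phantoms and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement and its pipeline

The frontomaxillary facial (FMF) angle is measured on the mid-sagittal
fetal profile between the superior margin of the palate and a ray from the
anterosuperior palate corner to the frontal bone; it is elevated in
trisomy 21. Manual measurement requires an experienced sonographer and is
subjective, which motivates an automated pipeline of three stages:

1. semantic segmentation of the two bony key components (palate, frontal
   bone) against background;
2. localisation of the three landmarks that define the angle — the vertex
   `V` (anterosuperior palate corner), a posterior point `P` on the
   palate's superior margin, and the outermost anterior frontal-bone point
   `F`;
3. the angle itself from the three points: with side lengths
   `a = |PF|`, `b = |VP|`, `c = |VF|` (Euclidean, in pixels), the angle at
   `V` is `θ = acos((b² + c² − a²)/(2bc))`, reported in degrees.

The vertex role is fixed to `V`: the measurement's two rays both emanate
from the anterosuperior palate corner, so of the three triangle angles
only the one at `V` is the FMF angle. `acos` arguments are clamped to
\[−1, 1\] (floating-point guard, documented behavior); collinear triples
return 0°/180° with a flag rather than an error, while a zero-length side
incident to the vertex is a degenerate-measurement error. Pixels are
assumed square: the law-of-cosines angle is invariant to uniform but not
anisotropic scaling, so anisotropic calibration is rejected rather than
silently mis-measured.

## Segmentation stage

The segmenter is an encoder–ASPP–upsampling design: a strided
convolutional stem to output stride 8, residual blocks whose later blocks
use dilation 2, then atrous spatial pyramid pooling with five parallel
branches — a 1×1 convolution, three 3×3 atrous convolutions (default
rates 12/24/36 at the full 480 px scale), and an image-level branch
(global average pooling, 1×1 convolution, broadcast) — concatenated,
fused by a 1×1 convolution, classified per pixel into three classes and
bilinearly upsampled to the input size.

Training uses class-weighted cross-entropy. The loss is the per-pixel
mean of `−ω_c log Q(c)` at the true class `c`; the background weight is
reduced (default `ω = (0.4, 1, 1)`) to counter class imbalance, since the
two bony structures together cover only a few percent of the frame.
Natural logarithm is used; any other logarithm base is a constant factor
absorbed into the learning rate. Optimisation is SGD (momentum 0.9,
weight decay 1e-4, initial LR 2e-3, batch 4) with polynomial decay
`lr₀·(1 − step/total)^0.9`; 0.9 is the conventional power for this
schedule. Augmentation draws a random scale in \[0.5, 2\], a horizontal
flip with probability 0.5, and a random crop to the input size; crops
extending past the border are padded with background (the generator's
anatomy never touches the frame edge, so padding is the less destructive
choice vs. rejecting such crops).

The backbone depth is parametric. A compact preset (`"small"`) is the
default and a `"tiny"` preset supports CPU-scale experiments; very deep
50-layer-class encoders offer nothing at phantom scale while making even
a single forward pass slow on one CPU, so they are intentionally not
bundled. Network weights use He initialisation; residual blocks
zero-initialise their closing convolution so each block is the identity
at initialisation — with no normalisation layers in the engine this keeps
activation variance flat at any depth.

Per-channel normalisation constants are recomputed from the training set
by default; explicit constants can be forced through the config (supplied
printed constants for the keypoint stage exceed 1 and cannot be \[0,1\]
pixel means, so recomputation is the default behavior).

Prediction takes the per-pixel argmax of the softmax scores, breaking
ties toward the lowest class index, and (by default) keeps only the
largest connected component per foreground class, which removes
speckle-like false positives. Images of other sizes are bilinearly
resized for inference and the mask mapped back by nearest neighbour.

## Keypoint stage

Landmarks are regressed as Gaussian heatmaps: each visible landmark is
rendered as an unnormalised Gaussian (peak 1, σ = 2 heatmap cells,
truncated at 3σ) centred at its heatmap-scale position `p/stride`;
invisible landmarks give all-zero maps. σ = 2 and stride 4 are the
conventional values for this network family. Centres that leave the
heatmap after the stride mapping are clipped to the border with a
warning; landmarks beyond the last cell centre (the final
`stride − 1` pixel band) therefore decode with slightly larger error
than the interior argmax bound of `stride·√2/2` px.

The network has two parallel branches: a stem of two 3×3 stride-2
convolutions (4× downsampling) and four bottleneck blocks; then a
full-resolution branch and a half-resolution branch that repeatedly
exchange information — downward via a 3×3 stride-2 convolution, upward
via nearest-neighbour interpolation plus a 1×1 channel-matching
convolution — before a final 1×1 convolution emits one heatmap per
landmark on the high-resolution branch. Branch widths (default 32/64,
tiny 16/24) and the number of fusion stages (default 2) are
configurable. Training minimises the mean squared error over all heatmap
cells with AdamW (lr 3e-3, β₁ 0.9, β₂ 0.999, ε 1e-8, weight decay 1e-4,
batch 16), with random rotation ±45° and scale \[0.65, 1.35\] applied
identically to the input and to the keypoints before encoding.

What the network sees is a genuine design choice in a two-stage
pipeline: the segmentation map alone, the raw image alone, or both. The
default is `concat` — the image channels plus the one-hot mask — which
honours the two-stage design while preserving intensity cues that
survive segmentation errors; `mask_only` and `image_only` are selectable
to study either extreme.

Decoding is plain argmax (ties: row-major first occurrence) mapped back
as `cell·stride`, exact on cell centres; an optional quarter-cell
refinement toward the larger axis neighbour is available behind a flag
but off by default, matching the plain-argmax description of the
method.

## The phantom simulator

The simulator provides what clinical data cannot at desk scale: exact
ground truth. Anatomy is deliberately schematic — the contract of the
pipeline is geometric, and schematic structures make truth exact:

* palate: a bright elongated quadrilateral whose superior margin runs
  from `V` to `P`, slightly thicker posteriorly (a documented feature of
  real palates on ultrasound);
* frontal bone: a bright circular-arc band whose closest point to `V` is
  `F`, with `angle(P, V, F)` equal to the requested angle **before
  rasterisation** — the stored keypoints are the constructed continuous
  points, so biometry on them reproduces the target exactly;
* image degradations applied to the image only, never to masks or
  keypoints: Gaussian boundary blur (default σ 1.2 px), unit-mean
  multiplicative speckle (`(1−s) + s·E`, `E ~ Exp(1)` — a squared-
  magnitude Rayleigh-type model; default s = 0.35) and, with probability
  0.3, a dark distal shadow wedge below the palate (acoustic shadow).

Cohort angles are drawn from `Normal(67.790°, 4.609°)` truncated to
(45°, 110°) — the clinical distribution the simulator emulates, with the
truncation keeping geometry renderable and the clinical range comfortably
inside. Per-sample jitter covers palate length ±15 %, thickness ±20 %,
frontal ray ±15 %, whole-construct rotation ±20° (so no fixed orientation
can be exploited) and vertex position ±5 % of the frame. Noise magnitudes
are not calibrated against any scanner — no quantitative noise
description exists to calibrate to — and are explicitly free knobs.

What passing tests on phantoms does **not** show: robustness to real
speckle statistics, device-specific signatures, anatomical variability
(nasal bone, lips, mandible as distractors), oblique non-mid-sagittal
planes, or pathological morphology. Results at phantom scale are
artifact-level checks of the pipeline's mechanics, not clinical claims.

## Evaluation statistics

Segmentation: one-vs-rest pixel counts give `PA = (TP+TN)/total`,
`IoU = TP/(TP+FP+FN)`, `Dice = 2TP/(2TP+FP+FN)`; a class absent from
both masks is undefined overlap and reported `NA`, never 0. (A published
variant of the IoU denominator with `TN` in place of `FP` contradicts
the Dice–IoU identity `Dice = 2·IoU/(1+IoU)` and is not implemented; the
identity is enforced by tests.)

Measurement agreement: MAE and MRE (reference in the denominator, must
be positive), mean difference ± SD (n−1 denominator), Pearson r with
two-sided p, ICC(2,1) — two-way random effects, absolute agreement,
single measures — from the ANOVA mean squares
`(MS_R − MS_E) / (MS_R + (k−1)MS_E + k(MS_C − MS_E)/n)` with the
standard F-based 95 % CI (Satterthwaite df), and Bland–Altman limits
`mean ± 1.96·SD` of the raw per-pair differences (limits always derive
from raw differences, not from rounded summary numbers). "Two-way
random" is the interpretation used for the absolute-agreement ICC;
absolute agreement is deliberate — it penalises systematic bias between
raters, which consistency-type ICCs hide. Normality is gated by
Shapiro–Wilk at α = 0.05 (the package's choice of test); when a column
fails, medians and ranges are reported alongside.

`simulate_rater()` turns known truths into a biased, noisy reader
(`truth + bias + N(0, sd)`), enabling junior/senior-expert-style
comparisons with known ground truth.

## Reproducibility and numerical choices

One global seed fans out deterministically: per-phantom seeds are
`seed·1000 + i`; the split, segmentation, keypoint and rater stages use
fixed offsets (+11, +21, +31, +41), so any stage can be re-run in
isolation. All randomised dataset operations sort sample ids before
shuffling (directory-order independence). Re-running a config reproduces
every CSV bit-for-bit; plots are exempt.

Coordinates are continuous, 0-based, origin at the top-left pixel
centre, x rightward and y downward, across every reader, writer and
network — a single convention kills the classic off-by-one landmark
bug. Softmax is computed with max-subtraction; cross-entropy clamps
probabilities at 1e-12; the `acos` argument is clamped at \[−1, 1\].
Checkpoints are self-describing (`config` + normalisation + weights).

## Desk-scale profile

`desk_profile()` fixes the problem sizes used by the end-to-end checks:
250 phantoms at 256×256, training split 180 after a 50-sample validation
carve-out and a 9:1 train:test split of the remainder; the tiny
segmentation backbone trained at 256 px input with ASPP rates 6/12/18
(rates scale with the feature-grid size — the full-scale 12/24/36 rates
would overshoot a 32×32 grid), 16 epochs; the tiny keypoint network at
256 px input, 16 epochs, with augmentation narrowed to rotation ±20° and
scale \[0.85, 1.15\] — the phantom generator already rotates every
construct by up to ±20° and jitters all lengths, so the full clinical
augmentation recipe on top of it doubles the pose variability and, at
tiny-model scale, stalls optimisation near the zero-heatmap baseline.
The desk profile also enables the quarter-cell decode refinement: at a
256 px frame with stride 4 the argmax quantisation alone contributes
roughly 1.5 px of landmark error, a substantial fraction of the tiny
models' total, and the refinement recovers most of it. These sizes are the package's choice of a
single-CPU experiment that still exercises every stage meaningfully;
landmark error is reported at the 256×256 scale.

## Known limitations

* The phantom is schematic; no claim of clinical performance follows
  from phantom metrics.
* The CNN engine is single-image (no batch dimension), single-threaded,
  CPU-only; batch size only controls gradient-accumulation granularity.
* The frontal-bone class is a thin curved band and segments less
  reliably than the palate at tiny-model scale; the keypoint stage's
  `concat` input lets image intensity compensate.
* Only 2-rater ICC designs are implemented; multi-rater designs and
  DICOM ingestion are out of scope.
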