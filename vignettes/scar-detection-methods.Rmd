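---
title: "Detecting myocardial scar on early contrast-enhanced cardiac CT: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting myocardial scar on early contrast-enhanced cardiac CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Myocardial fibrosis (scar) is normally assessed with late gadolinium
enhancement on cardiac MR, or with a dedicated late-phase acquisition on
contrast-enhanced cardiac CT (CCT). Both require either an extra modality or
extra contrast/radiation. In the *early* CCT phase — acquired routinely for
coronary assessment — scar is present but faint, often invisible to the eye.
`scarCCT` implements a pipeline that learns to detect scar at the level of
myocardial sectors directly from early-phase short-axis slices, using
late-phase tracings only to build training labels:

1. **Myocardium segmentation** (`segment_myocardium()`): delimit the left
   ventricular wall on each early-phase slice and mask everything else.
2. **AHA sectorization** (`assign_sections()`, `sectorize_slice()`): divide
   the stack into basal/mid/apical thirds and each slice into 6 (basal, mid)
   or 4 (apical) angular sectors of the 16-segment AHA model; the apical cap
   is excluded.
3. **Labeling** (`label_volume()`): each sector is labeled from the
   late-phase scar mask by its enhanced-area fraction: *scar* above a 15%
   threshold, *no scar* at exactly zero, *excluded* in between.
4. **Classification** (`train_cnn()`): a compact 2-D CNN classifies 85 × 85
   sector patches, trained with majority-class undersampling and evaluated
   with patient-wise k-fold cross-validation.
5. **Segment-level reporting** (`aggregate_aha()`, `segment_agreement()`):
   sector calls are pooled into per-patient 16-segment bull's-eye maps and
   scored against reference maps with per-segment Cohen's kappa.

Clinical data cannot ship with the package, so a seeded phantom generator
(`generate_case()`, `generate_cohort()`) provides paired early/late volumes
with ground-truth masks; every stage is exercised and tested against those.

## The phantom

Each slice models the LV as a bright blood pool (default 400 HU-like units)
inside a darker myocardial annulus (120) on a zero background, with radii
tapering linearly toward the apex and a small seeded jitter of the LV axis.
Scar is a wedge in angle crossed with a radial band of the wall —
subendocardial (inner third), midwall, subepicardial (outer third), or
transmural (full thickness) — spanning a run of consecutive slices. Noise is
additive i.i.d. Gaussian per voxel.

Two intensity choices matter:

* **Late-phase scar intensity** defaults to 260, i.e. a +140 contrast over
  healthy wall — bright delayed enhancement.
* **Early-phase scar contrast** defaults to 30% of the late contrast
  (intensity 162). The early phase is where detection happens, and how
  visible scar is there in real data is not quantified anywhere we know of;
  this ratio is a free parameter of the phantom, not an estimate of a
  clinical value.

What the phantom does **not** model: papillary muscles (segmentation still
merges enclosed bright islands into the pool, the rule real data needs),
beam hardening, motion, anatomical shape variation, or intensity texture
within tissue classes. Passing tests on phantoms therefore demonstrates that
the pipeline's machinery is correct and that the classifier can recover a
known signal; they say nothing about clinical accuracy, which would require
the original patient data.

## Segmentation

Pipelines in this area typically use an active-contour/region-growing
scheme whose exact variant is rarely specified. Ours: smooth the slice
(Gaussian, σ = 1 px, used only for mask estimation), estimate the
background level from the image border and the blood level from a 5 × 5
neighborhood of a seed (default: intensity-weighted centroid of the
top-decile pixels), grow the heart region from the seed through
tissue-intensity pixels, and split it at the endocardial boundary by a
second threshold midway between wall and blood. The wall level is estimated
from heart pixels below the background/blood midpoint — estimating it from
the whole region would be biased upward by the pool. Growth thresholds are
re-derived from these estimates (a first pass locates the region, a second
pass with the refined epicardial threshold recovers the wall edge
unbiasedly). Bright islands enclosed by the endocardial contour are merged
into the pool by hole-filling. A slice with no contrast (uniform intensity,
or no pool/wall separation) raises a "segmentation failed" error carrying
the slice index. `accept_external_mask()` is the hook standing in for
manual correction: it validates and flags ring topology but never modifies
the mask.

On phantom slices this recovers the annulus with Dice ≥ 0.95 at zero noise
and ≥ 0.90 at noise equal to 10% of the blood/wall contrast (the test
suite's `test-segmentation.R` and the acceptance checks compute this on
100+ seeded slices).

## Sectorization conventions

Several choices are under-determined by the usual clinical description and
are fixed here explicitly:

* **Slice order**: index 0 is the most basal slice; everything is documented
  base → apex.
* **Section split**: three contiguous groups of near-equal size; when the
  kept-slice count is not divisible by 3, extra slices go to the basal
  group first, then mid. (A fixed remainder rule is required for
  determinism.)
* **Angular reference**: sector 1 starts at `reference_angle` (default 0 =
  image "up"), measured visual-counterclockwise about the blood-pool
  centroid. Clinically the anchor is the RV insertion; phantoms have no RV,
  so the parameter is explicit instead of detected.
* **Pixel-to-sector assignment**: by the angle of the pixel center with
  half-open intervals, which guarantees the sector masks partition the
  myocardium exactly (asserted in tests as set equality).
* **Basal inclusion**: a basal slice is kept only if the wall fully
  surrounds the pool; the check demands 360° angular coverage with no gap
  larger than one pixel of angular quantization at the inner radius —
  parameter-free, like the apical-cap rule, which excludes apical slices
  whose blood pool has vanished (no enclosed background hole).
* **Slice mapping across stacks** (`map_slices()`): each target slice is
  assigned to the source slice whose physical interval contains the target
  center, stacks aligned at their first slice, centers beyond the source
  extent clamped to the last slice so the mapping always partitions.

## Labeling

The enhanced-area fraction rule is three-way: *scar* strictly above the
threshold (default 0.15), *no scar* only at exactly zero, and *excluded* in
the band in between. Descriptions of this rule are often two-way
("scar if > 15%, no scar otherwise"), but sector counts reported alongside
it are only consistent if partially covered sectors below the threshold are
excluded from both classes; the three-way rule is what this package
implements, and excluded sectors are dropped from both training and test
data (recorded in the run manifest). Areas are pixel counts — the ratio is
invariant to pixel spacing.

## Preprocessing, balancing, folds

Each retained sector is cropped to the bounding box of its mask on the
myocardium-masked slice, zero-padded to a centered square, resampled to
85 × 85 with bilinear interpolation, and z-scored to zero mean and unit
population variance over the patch. Per-patch (rather than dataset-level)
normalization removes patient-level intensity offsets and needs no global
pass. Training folds only are balanced by random undersampling of the
majority (no-scar) class, fixed per fold; test folds keep their natural
imbalance. Folds are patient-wise: every sector inherits its patient's
fold, so no patient contributes to both training and test data. On-the-fly
augmentation draws rotation (±15°), isotropic scale (0.9–1.1), translation
(≤10% of width) and horizontal flips, with a stream seeded per (epoch,
sample); the transform families are standard, the ranges are package
defaults.

## The classifier

Four stages of 3 × 3 convolution (32, 64, 96, 96 filters, ReLU) → 2 × 2
max-pooling → batch normalization (after pooling, not after convolution),
then three fully-connected layers (256, 64, 1) with 30% dropout at the
input of each during training and a sigmoid output; 788,993 trainable
parameters. Weights initialize from a zero-mean normal (sd 0.05 — the
distribution family is fixed, the scale is a package choice). Training
minimizes binary cross-entropy plus an L2 penalty (λ = 0.01 on convolution
and FC weights, not biases or batch-norm parameters) with Adam at an
initial rate of 10⁻³, batch size 32, at most 100 epochs. The plateau rule:
when the best validation loss is 6 or more epochs old, the rate is
multiplied by 0.2 (patience semantics — "no new best for 6 consecutive
epochs"); training stops when the rate falls below 10⁻⁷. The validation set
for the scheduler is a patient-wise 10% carve-out from the training folds;
the test fold is never touched during training. The classification
threshold on the sigmoid score is 0.5 — natural under a balanced training
distribution, and AUC is threshold-free; it is configurable.

There is no deep-learning framework dependency: the network, its backward
pass, and Adam are implemented in compiled code inside the package
(im2col + GEMM convolutions), with analytic gradients verified against
finite differences in the test suite. Numerical details: batch-norm ε is
10⁻⁵ with biased batch variances; max-pooling uses floor division (85 → 42
→ 21 → 10 → 5), so the FC head sees 5 × 5 × 96 = 2400 features; sigmoid
inputs are unclamped but the cross-entropy clips probabilities at 10⁻¹².
One consequence of short training schedules is that momentum-averaged
batch-norm running statistics remain dominated by their initialization, so
after training the running statistics are recalibrated by full passes over
the training set with the final weights (pooled per-chunk means and
variances); inference (dropout off, running statistics) is deterministic
given the weights.

## Evaluation

Per-fold accuracy, sensitivity, PPV, NPV (zero-denominator cases are
reported as undefined, never silently 0), and AUC computed as the
Mann–Whitney pair-ranking probability with ties counted ½. Fold scores are
averaged with a t-based 95% CI; the mean ROC curve is the vertical average
of fold ROCs on a fixed false-positive-rate grid. Sector calls aggregate to
per-patient 16-segment maps by majority vote within each segment, ties
calling scar (configurable; majority-with-tie-to-scar keeps sensitivity to
partial-segment scar), segments with no retained sectors marked excluded.
Predicted and reference maps are compared per segment across patients with
Cohen's kappa (large-sample standard-error CI, no variance correction),
excluded segments dropped pairwise, plus an overall agreement fraction.

## Problem sizes in the tests and acceptance script

The shipped checks use deliberately small study conditions chosen once: a
20-patient cohort (50% scar prevalence) of 6-slice, 96-pixel phantoms with
transmural scar over a 120° wedge and 4 slices, noise sd 10, and the
early-phase scar contrast boosted to the late-phase value — a cohort
*learnable by construction* — with 2-fold patient-wise CV and 15 epochs.
Under these conditions the cross-validated mean AUC exceeds 0.9, and a
shuffled-label control stays within ±0.1 of 0.5. The 15% labeling
threshold, architecture, optimizer and schedule are never altered from
their defaults in these runs.

## Known limitations

* The phantom's regular geometry makes segmentation and classification far
  easier than clinical CCT; reported phantom metrics are upper bounds of
  machinery correctness, not clinical performance estimates.
* The early/late contrast ratio is a free parameter (see above).
* 16 segments throughout; the apical cap (segment 17) is excluded by
  design, and no RV-insertion detection is attempted.
* Scar-burden quantification is out of scope: the output is presence or
  absence per sector/segment.
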