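---
title: "Predicting receptor status from nuclear morphometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting receptor status from nuclear morphometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Clinical estrogen-receptor (ER) status in breast carcinoma is determined by
immunohistochemistry, but nuclear morphology on routine H&E sections carries
correlated information: ER-negative tumours tend to show larger, more
pleomorphic nuclei. `nucleomorph` implements a hybrid pipeline that makes
this relationship learnable and, crucially, *inspectable*: instead of
feeding raw pixels to a network, it first reduces each image to a table of
biologically meaningful per-nucleus descriptors, encodes those as a sparse
multi-channel image, and trains a small fully convolutional network (FCN) on
weakly labeled patches. Because the network only ever sees pre-defined
features, the trained model can be reverse-engineered feature by feature.

The pipeline has five stages, each usable on its own:

1. **Segmentation** (`segmentImage()`): classical operators only.
2. **Snapshot container** (`TissueSnapshot`, XML/CSV readers and writers).
3. **Sparse encoding** (`encodeSnapshot()`): the 12-channel image.
4. **Model** (`buildNetwork()`, `trainNetwork()`, `predictHeatmap()`).
5. **Interpretation** (`digitalStain()`, `rankAndGroup()`,
   `groupSummary()`, `logisticBaselineTrain()`, `rocAuc()`, `aucCI()`).

A seeded synthetic generator (`generateSnapshot()`, `renderHE()`,
`generateCohort()`) provides ground-truth data for every stage.

## Segmentation

The recipe is deliberately classical: rescale to the 0.5 µm/px working
resolution with bicubic interpolation; keep the HSB brightness channel
(per-pixel max of R, G, B — hematoxylin-dark nuclei have low brightness);
intersect a global Otsu mask with a local adaptive mask (mean over a
radius-20 px ≈ 10 µm disc, minus a configurable offset `C`, default 0);
split touching nuclei with a distance-transform watershed; measure each
label.

Design choices where the recipe is under-determined:

* **Local threshold statistic.** Mean-minus-offset over a disc. The radius
  is the recipe's; the statistic and offset are ours (configurable).
* **Mask combination.** Logical AND of the global and local masks: the
  global mask finds cellular regions coarsely, the local mask carves fine
  boundaries inside them.
* **Despeckling.** A 3×3 morphological opening of the combined mask
  (default on). Without it, sensor noise on object-free regions percolates
  through the two thresholds into spurious "nuclei"; nuclei at the minimum
  area (8 µm² = 32 px) have radius ≥ 3 px and survive the opening intact.
* **Watershed flavour.** Euclidean distance transform, Gaussian-smoothed
  (σ = 1 px) so rasterisation bumps do not seed maxima, h-maxima
  suppression with h = 1 px (configurable), then flooding; every foreground
  pixel receives a label.
* **Filters.** Border-touching components and components below 8 µm² are
  discarded — both prevent degenerate measurements; both configurable.
* **Perimeter estimator.** Vossepoel–Smeulders weighted chain-code length
  (0.980 per axial step, 1.406 per diagonal, −0.091 per corner) over the
  traced boundary. A naive boundary-pixel count systematically
  underestimates the perimeter and pushes the circularity
  `4πA/P²` of a disc above 1; with this estimator a rasterised disc
  measures ≈ 0.97–1.0 and circularity is clamped at 1.
* **Ellipse fit and angle convention.** Major/minor axes come from the
  ellipse with equal second moments (axis length = 4·√eigenvalue of the
  pixel covariance, with the 1/12 pixel-square correction). The
  orientation θ is measured in degrees from the +x axis towards +y
  (image convention, y down), wrapped to (0, 180]; θ = 0 is identified
  with 180 as the same undirected axis.

Quality control is automated: `concordanceQC()` greedily matches predicted
to true centroids within a tolerance (2 µm default) and a segmentation
passes iff the matched-truth fraction strictly exceeds 0.70 — the same cut
used for visual scoring of segmentation overlays.

## The sparse 12-channel encoding

Each nucleus becomes a single nonzero pixel on a 2 µm/px grid (4× the
working resolution). Channels 1–6 store `major, minor, ratio, area,
perimeter, circularity` in raw µm-based units; channels 7–12 one-hot encode
the orientation into six 30° bins: bin j is active iff
`30(j−1) < θ ≤ 30j`.

Numerical decisions:

* **Placement, not resampling.** Nuclei are placed directly at
  `(floor(x_px/4), floor(y_px/4))`. Literal nearest-neighbour resampling of
  a sparse image would silently drop ~15/16 of nuclei; the floor map is the
  operative definition of the 4× reduction.
* **Collisions.** Two nuclei in one 2 µm pixel: the larger-area nucleus
  wins deterministically (ties: table order); the event is counted in the
  object.
* **θ = 0.** Remapped to 180 before binning.
* **Dihedral augmentation as channel permutation.** The point of the binary
  bins: a geometric transform of the image is exactly mirrored by a
  permutation of the angle channels (rotation by 90° shifts bins by 3;
  flips reverse them, k → 7−k; the two diagonal reflections swap bins 1/3
  and 4/6). `transformFeatureImage()` implements all eight elements, and
  the test suite proves `encode ∘ transform = transform ∘ encode`
  bit-exactly against a closed-form transform of the cell table. The only
  caveat: for θ exactly on a 30° bin edge the open/closed edges break the
  flip symmetry (a measure-zero set for continuous angle estimates);
  equivariance tests sample angles off the edges.

## The network

Six convolutional layers: five 3×3 feature convolutions with widths
(32, 64, 96, 128, 224), each followed by leaky ReLU (slope 0.01) and 2×2
max pooling (floor on odd sizes, so 100 → 50 → 25 → 12 → 6 → 3); dropout
(rate 0.5) immediately before a 1×1 single-logit classifier convolution; a
global mean over the logit map; and one batch-normalisation layer applied
to the scalar mean logit before the sigmoid. The defaults give 446,593
convolutional parameters (446,595 with the batch-norm affine pair), within
10% of 4.6×10⁵. Being fully convolutional, the network accepts any input
with both sides ≥ 32 px and returns a logit map shrunk by the five pooling
stages — the heatmap.

Decisions worth flagging:

* **Batch-norm placement.** Normalising the *scalar output* is unusual for
  CNNs but is what "one batch-normalisation layer producing
  well-distributed output predictions" amounts to; it decouples the
  network's raw logit scale from the loss. A practical consequence: the
  absolute cross-entropy can plateau around `−log σ(γ)` until the BN gain
  γ has grown, while the *ordering* of scores (hence AUC) converges much
  earlier. Inference uses running statistics, making prediction
  deterministic.
* **Single logit, not 2-way softmax.** Fixes the heatmap contract: logit
  > 0 means ER-negative evidence; the specimen score is
  `sigmoid(BN(mean logit))` ∈ [0, 1].
* **Input standardisation.** The six shape channels are standardised
  (train-set mean/sd at nucleus pixels) inside the model's input layer,
  on by default (`networkConfig(standardizeInput=)`): raw areas (~50 µm²)
  are two orders of magnitude larger than the one-hot bins and destabilise
  early training. The scaler is stored in the model, so inference is
  self-contained.
* **Optimiser.** Adam, lr 10⁻³ by default, fully seeded; dropout masks and
  patch sampling come from the R RNG so runs are bit-reproducible.
* **Two-phase weak-label training.** Patches (100 px = 200 µm) sampled
  uniformly from training images inherit the image label; each gets a
  uniformly random dihedral transform. Phase 1 holds out 20% of specimens
  (stratified) and monitors their patch loss; phase 2 adds them back.
* **Exact rotation invariance is *not* claimed.** Convolution does not
  commute with rotations of the input (a rot180 of the input corresponds
  to a rot180 of the *kernels* too), so scores under the eight dihedral
  transforms agree only approximately, to the extent augmentation has made
  them; the suite measures backend correctness against an independent
  plain-R forward implementation and finite-difference gradients instead.

## Interpretation

* `digitalStain()` upsamples per-location probabilities (nearest
  neighbour) and alpha-blends red into pixels with p strictly > 0.5.
* `rankAndGroup()` sorts patch scores ascending (stable ties) into equal
  groups of `floor(n/15)`, dropping the highest-score remainder — 11,161
  patches make 15 groups of 744 with 1 dropped.
* `patchStats()`/`groupSummary()` compute intra-patch means and
  **population** variances (divide by n; a documented, toggle-able
  convention) of the six shape features over the nuclei in each patch,
  then per-group inter-patch means with standard errors. Empty patches are
  flagged and excluded.
* The logistic baseline fits an unregularised maximum-likelihood logistic
  regression (optional L2 via glmnet) on the 12 standardised moments
  (6 means + 6 variances; angle bins excluded, as only shape features are
  plotted in the group analysis) of sampled training patches, and scores a
  test image as the mean predicted probability over its non-empty
  non-overlapping 64 px tiles.
* `rocAuc()` is the rank-based Mann–Whitney statistic with ties at ½,
  tested exactly against an O(n²) pair-counting oracle. `aucCI()` is a
  stratified percentile bootstrap (class sizes preserved) — the CI method
  is assumption-light and suits small specimen counts; it is our choice,
  not a prescribed one.

## The synthetic generator

`generateSnapshot()` draws nucleus positions from a Thomas cluster process
(Poisson parents, Gaussian offspring, points outside the extent rejected)
to mimic epithelial nests; per-nucleus area and axis ratio are log-normal,
orientation uniform on (0, 180] (or nest-aligned via
`orientation = "nest"` to exercise the angle channels); minor axis follows
from `area = π·major·minor/4`, perimeter from Ramanujan's approximation,
circularity from `4πA/P²`.

The defaults are the study conditions of the test suite, chosen once for
desk-scale learnability and explicitly *not* measurements: class 0
(ER-positive) area median 35 µm² with log-sd 0.25; class 1 (ER-negative)
median 55 µm² with log-sd 0.45 — larger *and* more heterogeneous, the
direction the real classifier is expected to learn; shared density
3000/mm²; parent density 60/mm² with cluster radius 20 µm; extent
400×400 µm (a 200×200 px feature image, large enough for 100 px training
windows while keeping a full cohort run on a single CPU in minutes).
Segmentation fixtures instead use an effectively unclustered field
(parent density = density), hard-core thinning (`minSpacing = 16` µm) and
a 10 µm border margin so that rendered nuclei are non-touching and not
border-clipped — recovery guarantees only make sense for such fields.

`renderHE()` draws each nucleus as a filled dark-purple ellipse over a
noisy eosin-pink background with per-nucleus intensity jitter. It is a
fixture for the segmentation recipe, not a stain simulation: there is no
stromal texture, no chromatin structure, no staining artefacts, no
overlapping-tissue effects. Consequently, green tests here demonstrate the
*mechanics* of the pipeline (correct operators, correct bookkeeping,
learnable planted effects) — they do not certify performance on real H&E,
where segmentation errors and biological variability dominate.

## Test and verification sizes

The suite's heavier runs, sized for a single CPU: segmentation recovery
uses ten rendered 200×200 µm fixtures (~20–30 nuclei each); learnability
uses cohorts of 100 specimens (50 per class, stratified 60/40 split)
trained for 50 epochs × 100 patches (5×10³ patch presentations, ~1/14 of
the full-scale schedule) with three seeds, majority vote, asserting
held-out specimen AUC ≥ 0.85 for the FCN and ≥ 0.75 for the logistic
baseline; with the planted defaults both typically reach 1.0. The
backend is verified against a plain-R forward reference and
finite-difference gradients at reduced widths.

## Known limitations

* The renderer's simplicity means segmentation is only validated on
  idealised ellipse fields.
* The watershed labels all foreground pixels; no one-pixel background
  ridge is drawn between touching objects (unlike the classical binary
  watershed), which can merge measurements if two nuclei touch *and* the
  distance transform has no saddle between them.
* Finite-difference gradient checks are performed away from the leaky-ReLU
  kink; at exactly zero pre-activation the subgradient convention (slope
  1) is asserted only implicitly.
* The batch-norm-on-output design couples calibration speed to the BN gain
  (see above); reported probabilities early in training are conservative
  even when the ranking is already good.
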