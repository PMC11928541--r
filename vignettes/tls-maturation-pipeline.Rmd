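---
title: "Classifying tertiary lymphoid structure maturation from dual CD21/CD23 IHC"
author: "tlsmat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying tertiary lymphoid structure maturation from dual CD21/CD23 IHC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Tertiary lymphoid structures (TLS) are organized lymphoid aggregates that
form in non-lymphoid tissue, notably in and around tumors. Their maturation
stage carries prognostic information: the most mature structures contain a
germinal center (GC), the site of B-cell proliferation and selection. On
dual immunohistochemistry with CD21 (red chromogen) and CD23 (brown DAB)
over a hematoxylin counterstain, the three stages are operationally defined
by marker positivity:

* **Aggregate** (code 0): CD21-/CD23- — a lymphocyte cluster without a
  follicular dendritic cell (FDC) network;
* **Non-GC TLS** (code 1): CD21+/CD23- — an FDC meshwork without a germinal
  center;
* **GC TLS** (code 2): CD21+/CD23+ — a germinal-center-containing, fully
  mature structure.

Manual staging is reproducible between trained raters but slow. `tlsmat`
implements an automated pipeline: pathologist-annotated TLS polygons
(QuPath-exported GeoJSON) are cut into non-overlapping 224x224-pixel tiles,
a three-class tile classifier scores each tile, and a tile-to-structure
aggregation rule assigns one maturation class per TLS. Evaluation uses
confusion matrices, accuracy and Cohen's kappa under patient-stratified
cross-validation.

## Tiling geometry

For each TLS the tile grid is anchored at the polygon bounding box's
top-left corner, floored to the pixel lattice. This makes each TLS's tile
set translation-covariant and reproducible without any global slide
registration (no anchor is dictated by the data format). Coordinates are
0-based, y-down, and tiles cover half-open intervals
`[x0, x0 + size) x [y0, y0 + size)`, so tiles of one TLS are disjoint by
construction.

A grid cell is retained iff the polygon covers at least `min_overlap_fraction`
(default 0.5) of the cell. Overlap is deliberately defined by **pixel-center
rasterization** — the number of pixel centers inside the polygon — rather
than by exact polygon clipping. The two measures differ by at most a
boundary band of pixels, but rasterization is the natural measure in the
image domain, matches what any pixel-level reimplementation computes, and
makes the retention rule exactly reproducible. It is implemented by an
exact row-scanline crossing algorithm, and the test suite checks it
cell-for-cell against an independent brute-force point-in-polygon oracle
(`mgcv::in.out`). The boundary-handling rule itself (which partially covered
cells to keep) is this package's decision; `min_overlap_fraction = 0` keeps
any intersecting cell for sensitivity analyses. TLS whose polygon retains no
cell are excluded and reported.

## The tile classifier

Training follows a fixed contract: cross-entropy-with-logits loss, minibatch
stochastic gradient descent with momentum 0.9, and a step-decay (StepLR)
learning-rate schedule `lr * gamma^floor((epoch - 1) / step)`. Seeds control
weight initialization and batch shuffling, so a run is bit-reproducible in
single-threaded execution. The checkpoint keeps the weights of the epoch
with the best validation accuracy (the earliest epoch on ties; the selection
rule is a package decision — monitoring validation accuracy is given, the
tie policy is not). The optimizer itself (SGD + momentum) is likewise a
declared default: it is the standard pairing with a StepLR schedule, and it
is configurable. Class weighting is available but off by default; uniform
weights reproduce the unweighted loss exactly.

Backbones are pluggable through a registry with a minimal contract: a
featurizer from a `224 x 224 x 3` tile to a fixed-length vector, and a
linear head producing 3 logits. The bundled `reference-small` backbone uses
8x8 block color means plus per-channel dispersions (195 features, 588
parameters) and trains in seconds on a CPU; on the synthetic data below it
reaches tile accuracies above 0.95, which is this package's stand-in for
full-scale fine-tuned deep backbones. Adapters for externally trained deep
models (`resnet50-class`, `vit-large-class`) accept a user-supplied
featurizer; no pretrained weights are distributed, and requesting them
without a weights file is an explicit error, never a silent random
initialization. Patient overlap between the training and validation
manifests is rejected as leakage.

## Aggregation methods

Seven rules collapse a TLS's tile predictions into one class, on the ordinal
encoding 0 < 1 < 2:

| method | definition |
|---|---|
| `majority` | most frequent tile label |
| `average` | mean label, rounded to the nearest class |
| `median` | median label, rounded (an even count can give a half-integer) |
| `mode` | most frequent tile label (alias of `majority`) |
| `soft_voting` | argmax of the element-wise mean probability vector |
| `custom` | GC if any GC tile, else Non-GC if any Non-GC tile, else Aggregate |
| `max_confidence` | label of the single most confident tile |

`mode` and `majority` are defined identically in the source methodology; any
intended difference is not recoverable, so they share one code path and the
equivalence is documented rather than invented. `average` and `median`
operate on the 0/1/2 encoding, which is only meaningful ordinally; whether
the original implementation rounded or truncated is unstated, so this
package rounds. Confidence is the tile's maximum class probability — the
standard reading of an otherwise undefined "confidence score".

**Tie policy.** Every tie — tied counts, tied mean probabilities, `.5`
roundings, equal confidences with different labels — resolves toward the
*more mature* class, consistent with the biological prioritization built
into the custom rule, and is flagged via `tie_broken` so analyses can
quantify how often ties occur.

**Error amplification.** The custom rule equals the maximum label present,
so a single false-positive tile flips a whole structure. For a
true-Aggregate TLS of `n` tiles, each independently misread as a more mature
class with probability `eps`, the mislabeling probability is exactly
`1 - (1 - eps)^n`: strictly increasing in `n`, about 0.54 already at
`eps = 0.05, n = 15` (the mean tiles-per-TLS). `custom_error_curve()` gives
the closed form and `custom_error_mc()` verifies it by simulation; this
mechanism explains why max-confidence aggregation is the more robust rule
under tile noise, and the package's acceptance checks reproduce that
ordering.

## Evaluation

`confusion_matrix()` counts true (rows) against predicted (columns) classes.
Normalization is by true-class row by default, matching per-class
correct-prediction rates (column normalization is available behind a flag);
zero-support rows are reported as undefined, not as zeros. Cohen's kappa is
the unweighted `kappa = (p_o - p_e) / (1 - p_e)` with `p_o` the observed and
`p_e` the chance agreement from the marginals; the degenerate case
`p_e = 1` returns an explicit undefined marker. Agreement bands use the
conventional cutpoints (minimal <= 0.20, fair to 0.40, moderate to 0.60,
substantial to 0.80, almost perfect above), implemented as half-open
intervals closed at the lower edge because the prose convention leaves gaps
between 0.20 and 0.21. Note kappa <= accuracy is *not* an invariant and is
not asserted; instead the tests check kappa = 1 iff off-diagonals vanish,
kappa ~ 0 under independence, and invariance under simultaneous class
permutation, plus numerical agreement with `e1071::classAgreement` as an
independent implementation.

**Patient-stratified splits.** All of a patient's TLS stay in one partition.
`stratified_patient_splits()` first divides patients into `k` class-balanced
test folds (every patient is tested exactly once), then splits each fold's
remainder into train and validation at the requested ratio. Balancing works
on per-patient TLS class profiles: a capacity-constrained greedy pass
followed by a deterministic steepest-descent swap refinement on the summed
squared deviation from each group's pro-rata class target. Stratification on
TLS class counts (rather than tile counts) is a package decision — the
source wording "classes proportionately represented" is ambiguous. Exact
partition sizes use the largest-remainder method; the published cohort's
410/113/133 patients out of 656 correspond to ratios (0.625, 0.172, 0.203)
and are recovered exactly. A class carried by fewer patients than folds
triggers an explicit infeasibility warning with best-effort assignment.
Cross-validation reports all folds symmetrically; selecting a best fold post
hoc is a reporting choice, not an algorithm, and is not replicated.

## The synthetic generator

Because the underlying patient cohort is not public, the package ships a
synthetic dual-IHC generator so every stage is testable end-to-end with
known ground truth. It emulates, at the level of class-defining signal:

* hematoxylin-like background with gentle texture and additive pixel noise
  (`noise_sd`, default 6 on the 0-255 scale);
* TLS footprints as perturbed-ellipse blobs (random low-order radial
  harmonics), so tiling sees irregular boundaries; footprint areas are sized
  as `n_i * tile_size^2` with `n_i ~ 1 + Poisson(mean - 1)`, and polygon
  vertices are rescaled so the shoelace area matches the target exactly —
  this makes the expected retained-tile count track `mean_tiles_per_tls`
  (default 15, the cohort mean);
* CD21 as a red meshwork pattern across the footprint, CD23 as DAB
  germinal-center foci (patterned plus at least one explicit focus blob, so
  GC presence is guaranteed by construction);
* per-structure multiplicative stain-intensity jitter (`intensity_jitter`,
  default +/-0.3), occasional occluding gray artifacts (`artifact_rate`,
  default 0.05), and a default class mix of 0.333 / 0.162 / 0.505
  (Aggregate / Non-GC / GC), matching the 33,399 : 16,242 : 50,604 tile
  imbalance of the annotated cohort;
* placement on a jittered grid, which guarantees disjoint polygons in O(n)
  and turns an overfull canvas into an explicit placement error.

No quantitative stain statistics are available for the cohort, so the
default colors and noise levels are free parameters chosen once to look like
dual-IHC at low magnification; they are not calibrated to any cohort.
Pixel-level stain dominance is defined by chromaticity differences (red:
`R - G >= 0.35`; DAB: `0.06 < R - G < 0.35` with `G - B >= 0.06`), which are
invariant to the multiplicative jitter; a fixed threshold classifier on
these fractions recovers the true class of generated tiles with >= 99%
accuracy, guaranteeing the learning task is solvable at desk scale.

What the generator does **not** emulate: nuclei or any cell-level
morphology, H&E appearance, scanner formats, tissue folds beyond simple
artifact blobs, or the correlation structure of real slides. Green tests
therefore demonstrate that the pipeline's machinery — geometry, training
contract, aggregation, evaluation, serialization — is correct, not that any
particular accuracy transfers to real whole-slide images.

`corrupt_predictions()` complements the image path: it turns ground truth
into noisy tile predictions with a controlled error rate and confusion
kernel, with per-tile confidence drawn from a range so confidence-based
aggregation remains meaningful. It drives the noise-robustness and
error-amplification simulations.

## Parameters that matter

| parameter | default | units / meaning |
|---|---|---|
| `tile_size` | 224 | px; tile side (smaller values for desk-scale tests) |
| `min_overlap_fraction` | 0.5 | fraction of a cell the polygon must cover |
| `mean_tiles_per_tls` | 15 | expected retained tiles per TLS |
| `class_mix` | (0.333, 0.162, 0.505) | P(Aggregate, Non-GC, GC) |
| `intensity_jitter` | 0.3 | multiplicative stain-intensity half-range |
| `artifact_rate` | 0.05 | P(artifact blob per tile/TLS) |
| `noise_sd` | 6 | additive pixel noise SD, 0-255 scale |
| `epochs`, `learning_rate`, `lr_step_size`, `lr_gamma` | 10, 0.1, 4, 0.5 | StepLR training contract |
| `momentum` | 0.9 | SGD momentum |
| `tint_alpha` | 0.4 | class-color blend fraction in visual outputs |
| `ratios` | (0.625, 0.172, 0.203) | patient shares of train/validation/test |

The training hyperparameters are declared defaults, not values inferred from
the source methodology (which states the loss, the scheduler and the use of
seeds, but not the optimizer settings).

## Problem sizes used by the tests

The test suite runs entirely on generated data at sizes chosen to exercise
every contract while staying desk-scale: slide-level tests use 48-56 px
tiles on slides of up to a few hundred TLS (the geometry is scale-free);
the end-to-end recovery experiment trains the reference backbone on
3 x 500 / 3 x 100 full-size 224 px tiles and evaluates 45 held-out TLS of
~15 tiles each; Monte-Carlo checks use 10,000 replicates; the stratified
split contract is checked on a 100-patient cohort. `scripts/acceptance.R`
re-runs the same computations from scratch for any seed.

## Visualization conventions

Rendered outputs follow the display numbering 1/2/3 (Aggregate/Non-GC/GC)
with blue/green/red tints; internal encoding stays 0/1/2 and the mapping is
centralized in `class_colormap()`. The blend factor (0.4) keeps tissue
texture visible under the tint, and grid cells without tissue are filled
white in mosaics to distinguish absence from any class color — both are
package decisions where the source states none.

## Known limitations

* The reference backbone is a linear model on color summaries: sufficient
  for the chromogen-defined synthetic classes, not a substitute for deep
  features on real histology.
* Automated TLS *detection* is out of scope; the pipeline starts from
  polygon annotations.
* Real accuracies on the original cohort (or any external cohort) cannot be
  reproduced without the slides; the package's quantitative claims are about
  its own contracts on synthetic data.
* Pyramidal TIFF support reads level 0 only; vendor WSI formats (e.g. mrxs)
  are not supported — interchange is PNG/flat TIFF + GeoJSON + CSV.
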