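---
title: "Classifying lung parenchyma texture with a multi-dimensional CNN ensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying lung parenchyma texture with a multi-dimensional CNN ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungtex)
```

## The problem

Interstitial lung abnormalities (ILA) — subtle ground glass, reticulation,
nodularity, linear scars and subpleural lines on chest CT — can precede
clinically overt interstitial lung disease, and emphysema frequently coexists
with them in smokers. `lungtex` classifies small CT neighbourhoods into eight
parenchymal patterns: normal parenchyma (NP), five interstitial subtypes (GG,
RETIC, NOD, LINSC, SUBPL) and two emphysema subtypes (paraseptal PS,
centrilobular CL). Classifying every lung voxel by its surrounding patch
turns the patch classifier into a whole-lung labeling and a quantitative ILA
burden score.

## The model

Seven convolutional networks see the same annotated point through three
representations:

* **2D** — a 48 × 48 axial patch (`BCNN2D`, plus a multi-stage and a
  multi-context variant);
* **2.5D** — the axial, sagittal and coronal 48 × 48 planes through the
  point, stacked as three input channels (`BCNN2p5D`, `MSTAGE_CNN2p5D`);
* **3D** — a 48 × 48 × 7 slab of consecutive axial slices (`BCNN3D`,
  `MSTAGE_CNN3D`).

The patch size is fixed in voxel units and is chosen to cover a secondary
pulmonary lobule, the anatomic unit in which these textures live. All
convolutions are 3 × 3 (or 3 × 3 × 3): local texture, not global anatomy,
carries the signal, so small receptive-field increments with little pooling
are preferred, with a batch-normalization step after every pooling step.
The *multi-stage* variants branch mid-level features past the remaining
blocks, global-average-pool them and concatenate them with the final
features before the dense head, so the classifier sees two receptive-field
scales at once. The *multi-context* variant runs a parallel convolutional
path over a twice-larger neighbourhood (96 × 96, average-pooled back to
48 × 48). Member probabilities are fused linearly,

$$Y(x) = \sum_{i=1}^{7} w_i \, P_i(x),$$

and the predicted class is the argmax of \(Y\) (ties break to the lowest
class index, a documented and tested rule). The fused score is deliberately
not renormalized; the decision is invariant to positive rescaling of the
weights.

### Ensemble weight search

The weights \(w \in [0,1]^7\) are optimized on held-out validation
predictions only — members are never retrained inside the search. The
default sampler is a Tree-structured Parzen Estimator: observed trials are
split at the `gamma = 0.25` quantile of their objective scores, each set is
modelled with per-dimension truncated Gaussian Parzen densities, and each
trial evaluates the candidate (of 24 draws) maximizing the good/bad density
ratio. The objective defaults to one minus macro balanced accuracy
(configurable to one minus macro geometric mean, or cross-entropy). Uniform
random search (`RS`) and majority voting (`MVR`) are provided for
comparison; the Bayesian-optimization method name (`BO`) is accepted and
executed with the TPE engine, recorded as such in the search metadata,
since the samplers behave interchangeably on this 7-dimensional box and no
Gaussian-process backend is required that way.

Two deliberate design choices make the search well-behaved and testable:
the trial history is *seeded* with the uniform-weight vector and all seven
one-hot vectors before any random proposal. One-hot weights reproduce each
single member exactly, so the optimized ensemble can never score worse than
the best member — a structural guarantee the test suite asserts — and the
uniform start covers the unweighted-average baseline.

## Keeping small training sets honest

Four mechanisms limit overfitting, all on by default (`train_config()`):
L2 penalty `0.0025` on convolution/dense weights only, dropout `0.5` on the
dense head, early stopping with patience 30 epochs (the returned parameters
are always those of the best-validation epoch), and two kinds of data
augmentation:

* **Geometric** (rotation ±15°, shifts ±3 px, shear ±8°, flips) is applied
  during class balancing to the under-represented classes, bilinear with
  mirror boundaries, about the patch centre.
* **Sponge-model density augmentation** encodes a physiological prior: lung
  tissue mass is conserved over the respiratory cycle, so a volume change
  from \(V\) to \(V+\Delta V\) rescales density (attenuation above air,
  HU + 1000) by \(V/(V+\Delta V)\). Random \(\Delta V \sim U(-100, 100)\)
  mL emulates mild inspiratory-level differences between acquisitions. Mass
  conservation holds to 1e-9 relative in the implementation and is asserted
  as such. When a lung mask is available, \(V\) is the masked volume
  (`lung_volume_ml()`); otherwise a nominal 5000 mL default stands in, and
  both the range and the air reference (−1000 HU) are configurable.

The training roster is equalized across classes: classes with at least 800
annotated points contribute exactly 600 training points; smaller classes
contribute ⌈0.75 n⌉ points and are augmented (sources drawn with
replacement, transforms recorded in the roster) to 600, giving a balanced
4800-entry roster that is split into 10 stratified cross-validation folds.
All leftover points form the skewed test set. A subject-level variant holds
out whole subjects (all eight classes represented) so no subject leaks
across the split.

## Evaluation metrics

Per class, one-vs-rest sensitivity and specificity are combined into
\(GM = \sqrt{SN \cdot SP}\) and \(BA = (SN + SP)/2\); macro values are
unweighted means over the eight classes, equalizing class importance under
the heavily skewed test sets. The geometric mean is computed from the
*rates*, not from raw TP·TN counts: only the rate form is dimensionally a
companion to BA, and it is the identity every published per-class row of
this family of results satisfies, so the package treats the rate form as
the intended definition and documents the choice. Undefined metrics (a
class with no true test samples) raise an error naming the class rather
than silently reporting 0. Macro-averaged ROC curves interpolate per-class
one-vs-rest curves (built with pROC from renormalized fused scores) onto a
common false-positive-rate grid.

## Whole-lung labeling and ILA scoring

`classify_scan()` extracts and classifies patches at the nodes of a fixed
sampling grid (default 5 × 5 × 5 voxels) inside the lung mask, then assigns
every other in-mask voxel the label and certainty of its nearest classified
node (Euclidean distance in voxel units, ties to the lowest node index);
spacing 1 is exhaustive classification, and grid nodes agree exactly
between spacings. The certainty of a voxel is the renormalized probability
of its predicted label. The ILA score is the percentage of lung voxels
carrying any interstitial label with certainty *strictly* greater than a
threshold (default 0.95); emphysema labels are excluded from the score by
default (configurable), and the score is non-increasing in the threshold.
`ila_curve()` exports the full threshold sweep.

## The phantom generator

`generate_phantom()` builds parametric CT volumes for testing: an elliptic
"lung" at −850 HU plus Gaussian noise (sd 25 HU) inside an air background,
with eight lesion textures whose contrast (+150 HU ground-glass plateaus,
+300 HU lattices/streaks/bands, +400 HU nodule clusters, −980 HU emphysema
pockets/holes) and placement (subpleural classes within 5 voxels of the
border, centrilobular holes central) mirror the geometry of the real
patterns. Realism is explicitly *not* a goal; separability and placement
plausibility are, so that the learning pipeline, the confusion structure of
adjacent patterns and the full-lung scorer can be exercised end to end
without clinical data. Passing tests on phantoms therefore demonstrate that
the machinery learns, fuses and scores correctly — not that the clinical
performance of any real cohort would be reproduced; phantoms lack scanner
noise spectra, reconstruction-kernel effects (beyond an optional Gaussian
blur toggle that tags patches B35), respiratory motion and anatomic
context such as vessels and airways.

## Numerical and protocol choices

* Annotation files store 0-based voxel indices; in R everything is 1-based,
  converted at the file boundary.
* Attenuation normalization pools all voxels of the training + validation
  patches and uses the *population* standard deviation — the difference
  from the sample form is negligible at these counts but is pinned for
  bit-reproducibility.
* Patch borders: mirror reflection by default (subpleural points sit near
  the lung border), with a strict mode that errors instead.
* The 75% training allocation for small classes rounds *up*; this is the
  rounding consistent with the published per-class train/test counts.
* The 3D architectures use global average pooling before the dense head:
  flattening a 48 × 48 × 7 feature volume would put ~8 million parameters
  into one dense layer, against the design goal of keeping members at or
  around one million parameters. In-plane-only pooling preserves the thin
  z-extent of the slab.
* Weight initialization is seeded He-uniform; training, shuffling, dropout
  and every search are reproducible from explicit seeds, and re-running a
  pipeline stage with the same configuration reproduces its artifacts
  byte-for-byte.
* Desk-scale problem sizes used throughout the test suite and the
  acceptance script — 100 phantom patches per class, member widths (8, 8,
  16) for the reference 2D baseline and (4, 4, 8) for the remaining
  members, 8–15 epochs, with a higher learning rate (0.003) for the 3D
  members whose global-average-pooled heads converge slowly at such tiny
  widths — were chosen as the smallest configuration at which every member
  clearly exceeds chance and the 2D baseline exceeds 80% validation
  accuracy; all widths, epochs and rates are ordinary parameters for real
  use, where the tuned defaults apply.

## Limitations

* DICOM series input is not parsed; volumes must arrive as NIfTI or NRRD.
  Lung segmentation is an input (mask), not a feature.
* Grad-CAM diagnostics cover the 2D chain and multi-stage topologies (the
  representative members); other members raise an informative error.
* The subject-level ILA detection step (logistic regression over per-scan
  scores against visual reads) requires a clinical cohort and is out of
  scope; the per-scan score export it would consume is provided.
* The CNN engine is compact by design (im2col convolutions in C++, Adam,
  batch-norm, dropout); it is single-threaded apart from BLAS and is meant
  for patch-scale models, not for large-scale GPU training.
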