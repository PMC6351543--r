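---
title: "Cascaded tumor-region segmentation of whole-slide images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cascaded tumor-region segmentation of whole-slide images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wsicascade)
```

## The problem and the method

A whole-slide image (WSI) of a stained lymph-node or breast section holds
billions of pixels at full (40x) magnification. Detecting metastatic tumor
regions at that resolution with a sliding-window classifier is accurate but
slow, and yields only a coarse probability map (one value per 128-px stride,
a heatmap with 1/128 the side of the slide). Dense semantic segmentation
gives refined boundaries (1/8 side) but is far too slow to run over an
entire slide, most of which is glass or normal tissue.

`wsicascade` implements the two-stage cascade that resolves this tension:

1. **Tissue preselection.** The slide at 1.25x magnification is converted
   to HSV and the saturation (S) channel is thresholded by Otsu's method.
   Stained tissue is colored (high S) while glass background is near-gray,
   so the high-S side is foreground. This removes most of the slide before
   any model runs.
2. **Rough pass.** A patch classifier scores 299 x 299 patches at 40x on a
   128-px stride over tissue, giving a rough heatmap with 1/128 the slide
   side. Cells with probability strictly above 0.5 become *candidate tumor
   regions*.
3. **Dense pass.** A semantic segmenter — whose output raster is
   downsampled 8x relative to its input — is run only on large tiles
   (2560 x 2560 at 40x) that touch candidate regions, on an aligned grid
   with half overlap (stride 1280). Per-tile outputs are stitched into a
   whole-slide heatmap with 1/8 the slide side by *overlap averaging*: the
   value at heatmap position $(x, y)$ is

   $$p_h(x,y) = \frac{1}{n}\sum_i p\!\left(\tfrac{x_i}{8}, \tfrac{y_i}{8}\right),$$

   the mean over the $n$ tile predictions covering that position.

Because most tissue is normal, restricting the dense pass to candidate
regions cuts the number of segmented tiles by an order of magnitude while
leaving the refined boundaries intact — the cascade's entire point.

Training utilities follow the same conventions: the classifier's *patch
loss* is mean binary cross-entropy of patch probabilities against patch
labels (a patch is a tumor patch iff it contains at least one annotated
tumor pixel); the segmenter's *pixel loss* is binary cross-entropy between
the $(L/8)^2$ output pixels and the level-0 mask sampled at the stride-8
lattice, $m(8x, 8y)$, normalized by $(L/8)^2$. Patch sets are balanced 1:1
(all tumor patches, normals subsampled) and augmented with flips,
right-angle rotations and mild color jitter.

## Models are pluggable; oracles make the pipeline testable

Training deep networks is out of scope here. The package defines the two
inference contracts (`classifier_model()`, `segmenter_model()`) that any
model — a CNN behind a socket, an R function, anything — can satisfy, and
provides *oracle models* backed by the ground-truth mask for testing:

* `oracle_classifier(gt, noise_sd)` scores a window
  `clip01(I[window touches tumor] + N(0, noise_sd))`;
* `oracle_segmenter(gt, flip_rate)` returns the stride-8-sampled ground
  truth with each lattice value independently flipped with probability
  `flip_rate`, emitted as probabilities 0.1/0.9.

Oracle noise is keyed on (model seed, window origin), so predictions are
reproducible and independent of evaluation order. With zero noise the
cascade must reproduce the lattice-sampled ground truth exactly wherever it
segments — the test suite asserts exactly that.

## Evaluation

* **Slide AUC** — each slide is scored by its maximum heatmap probability;
  AUC is computed as the Mann–Whitney statistic with midranks for ties.
* **FROC** — lesions are 8-connected components of the ground-truth mask at
  heatmap scale; each connected component of the thresholded heatmap yields
  one detection at its argmax, scored by its maximum. Sweeping all distinct
  detection scores gives sensitivity versus average false positives per
  slide; the FROC score is the mean sensitivity at 0.25, 0.5, 1, 2, 4 and 8
  FPs/slide (the Camelyon convention — the rates are not dictated by the
  method itself), linearly interpolated and clamped at the curve ends.
* **mIoU / Tumor-mIoU** — per-slide two-class IoU from pixel confusion
  counts; mIoU averages the per-slide mean IoU over all slides, Tumor-mIoU
  averages the tumor-class IoU over tumor slides. A class absent from both
  prediction and truth scores IoU 1, so a normal slide predicted all-normal
  is perfect rather than undefined.
* **Bootstrap CIs** — slides are resampled with replacement (same cohort
  size), the metric recomputed, and the 2.5/97.5 percentiles over 2000
  seeded replicates reported.

## Synthetic slides: what they emulate, and what they do not

`synth_spec()` / `generate_slide()` produce seeded pyramidal slides with a
level-0 ground-truth mask, emulating exactly the structure the pipeline
relies on:

* white glass background; colored tissue (pink) and tumor (purple) regions
  separable on the HSV-S channel, with mild Gaussian color noise
  (sd 6 of 255) so histograms are not degenerate;
* tissue as a union of random ellipses matched to a target area fraction
  within 0.03 (default 0.25, a typical tissue coverage for a lymph-node
  section scan);
* tumor as smooth harmonically-perturbed blobs clipped to tissue (default
  two blobs of radius 150–400 px, i.e. lesions a few hundred pixels across
  — larger than one rough-heatmap cell, so candidate selection can see
  them on a desk-scale slide);
* a pyramid built by exact 2x mean pooling down to a 64-px side, so
  level-k reads are analytically related to level 0.

They do **not** emulate cell-level morphology, stain variation, tissue
folds, pen marks, or scanner artifacts. Passing tests therefore certify the
*geometry, bookkeeping and statistics* of the pipeline — coordinate
mapping, tiling, stitching, thresholds, metrics — not the discriminative
power of any model on real histology; that depends entirely on the plugged
models.

## Numerical and design choices

* **Coordinates** are 0-based, `(x = column, y = row)`, windows half-open;
  stitching arithmetic is exact integer division because tile origins are
  kept divisible by 8 (dense) and mapped by `floor` everywhere else.
* **1.25x = level-0 side / 32** (40x / 32); level 5 when stored, otherwise
  the deepest level pooled further.
* **Otsu** maximizes between-class variance exhaustively over the 256 bins;
  ties break to the smallest threshold for determinism. The S channel is
  integerized as `round(255 (max - min) / max)` (0 when max = 0) to keep
  the histogram exact. A slide whose S histogram has all mass in one bin
  (e.g. pure synthetic white) is rejected as degenerate rather than
  thresholded arbitrarily.
* **Edge handling.** Rough grids add a final window flush with each slide
  edge so no tissue is missed; dense grids instead extend one stride past
  the edge (keeping origins on the stride lattice, hence divisible by 8)
  and overhanging reads are white-filled, since slide background is white.
* **Candidate threshold** is strict (`p > 0.5`): a cell exactly at 0.5 is
  not a candidate. Same rule for heatmap binarization.
* **"Centered on candidate pixels"** is realized as an aligned 1280-stride
  grid covering all candidate cells. Literal per-pixel centering would
  create one 2560-px tile per candidate pixel; the aligned grid preserves
  the half overlap and coverage at a bounded tile count.
* **Rough heatmap geometry.** A 299-px window at stride 128 contributes its
  scalar to the single cell at `(floor(x/128), floor(y/128))` — one cell
  per window, which is what produces a 1/128-side map; duplicate
  contributions to a cell are averaged by the same rule as dense stitching.
* **Determinism.** Tile plans are row-major sorted before prediction and
  accumulation, fixing floating-point summation order; repeated runs are
  bit-identical.
* **Loss clipping** at `1e-7` bounds the cross-entropy for saturated
  predictions.
* **Heatmap files** are single-channel IEEE float32 TIFFs (written by a
  minimal built-in encoder since the available TIFF bindings write integer
  samples only; reading goes through libtiff) — bit-exact round trips at
  float32 precision. Masks are 8-bit PNGs. Polygon exports use the ASAP
  XML schema so results open directly in the ASAP viewer.
* **Polygons** are outer contours (Moore boundary tracing) of 8-connected
  components; holes are not exported, and components under 4 heatmap
  pixels are dropped as noise (configurable).

## Problem sizes used by the test suite

Unit tests run at 512–1024 px slides with 10x-scaled-down tile geometry
(256/128); the end-to-end suite and `scripts/acceptance.R` use a 16-slide
cohort (8 tumor, 8 normal) of 4096^2 slides with the method's full
2560/1280 tile geometry, which a single CPU core handles in a few minutes.
These sizes exercise every geometric regime of the method (multi-tile
overlap, edge tiles, candidate-restricted plans) while remaining desk-scale.

## Known limitations

* **Single-coverage borders amplify prediction noise.** Interior positions
  of a half-overlap tiling receive 4 predictions and overlap averaging
  suppresses independent per-tile noise strongly (a lattice flip survives
  binarization only if 3 of 4 predictions agree on it). But the outermost
  stride-wide band of any tiled region — of the slide itself, or of a
  candidate-restricted plan — receives a single prediction, where noise
  passes through unattenuated. On desk-scale slides these bands are a
  substantial share of the covered area, so with noisy segmenters the
  tumor-class IoU degrades well below what interior-only coverage would
  give. With exact models the cascade is exact; with real models on real
  slides (lesions large relative to the 2560-px tile) the band share is
  far smaller.
* The pyramid dialect is strict (page k = level k, 2x per level, RGB
  8-bit); real scanner formats need an adapter backend.
* FROC emits one detection per connected heatmap component; fragmented
  lesions or merged components shift counts at aggressive thresholds, a
  known property of component-based candidate extraction.
* The CLI's `rough`/`cascade` commands run the oracle models against a
  supplied ground-truth mask: they demonstrate and test the pipeline
  end-to-end but are not a trained detector.
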