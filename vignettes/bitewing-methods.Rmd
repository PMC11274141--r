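---
title: "Methods: segmentation and edge enhancement of bitewing radiographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation and edge enhancement of bitewing radiographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bitewing)
```

## Scope and model

A bitewing radiograph images the crowns of upper and lower posterior teeth in
one frame, separated by a dark occlusal band. Dental calculus — mineralized
plaque — accumulates on the proximal (neighbor-facing) surfaces and appears
as subtle bright deposits at tooth edges. This package implements the
classical processing chain that prepares such images for calculus screening:

1. **Segmentation**: isolate each tooth as its own crop, split vertically
   into two proximal halves.
2. **Enhancement**: denoise each crop and overlay its edge structure so the
   deposits become explicit.
3. **Dataset preparation**: balance the two classes and split into
   train/test/validation pools.
4. **Evaluation**: confusion-count metrics and PR-curve mean average
   precision for detectors.

Everything is deterministic given its inputs and configuration; the only
random components (phantom generation, augmentation choice, shuffling) run
from explicit integer seeds through an isolated RNG scope that never
perturbs the caller's session.

## Coordinates and the image carrier

Images are plain numeric matrices with values in [0, 255]; binary images
restrict values to {0, 255} with white = 255 the foreground. All public
coordinates — bounding boxes, cut columns, row indices — are 0-based and
half-open (`[x0, x1) × [y0, y1)`, x = column), matching annotation formats
such as YOLO and making box arithmetic exact (`area = (x1-x0)(y1-y0)`).
Matrix subscripts inside R remain 1-based as usual; the two conventions meet
only inside accessor helpers.

## Segmentation by projection profiles

The segmenter makes every cut decision on a simplified raster but extracts
pixels from the untouched original:

* **Mean filter** (default 3×3): windowed average, rounded half-up. This is
  the smallest standard denoising window; larger kernels blur the narrow
  interdental gaps the later stages depend on.
* **Global binarization at 170** with a strict rule: a pixel of exactly 170
  maps to black. Tooth enamel sits well above this threshold, background and
  the occlusal band below it.
* **Jaw split**: the horizontal projection profile (per-row sums of the
  binary image) is minimized over the central 50 % of rows. The central
  restriction exists because dark frame borders would otherwise tie or beat
  the occlusal band. Ties — the band is several rows of exact zeros — break
  to the midmost tied row.
* **Interdental cuts at 400**: per-jaw vertical profiles are scanned for
  maximal runs of columns below 400. On a binary profile with white counted
  as 255 this admits columns containing at most one white pixel, which is
  the correct reading for a gap column; the threshold is configurable.
  Each run collapses to its center column; runs touching the image border
  are discarded (margins are not gaps). When a jaw yields no cut at all the
  pipeline raises a stage-named condition (`bitewing_stage_error`) rather
  than returning an empty result.
* **Boxes with a 50 px margin**: consecutive cuts (plus the borders) bound
  one tooth each; every box is widened by 50 px per side and clipped, so
  tooth edges — where calculus sits — are never truncated. `n` cuts give
  `n + 1` boxes by construction.
* **Halving**: each crop splits into columns `[0, ⌊w/2⌋)` and the remainder.
  Halving happens after cropping and before enhancement, so each enhanced
  image carries exactly one proximal edge of interest.

## The enhancement pipeline

Stage order is fixed: median → bilateral → adaptive binarization →
morphology → Canny → overlay. Each intermediate can be retained
(`keep_stages = TRUE`) for inspection.

* **Median filter** (3×3): exact order statistic; removes impulse noise
  without shifting edges.
* **Bilateral filter** (radius 4, σ_spatial = 2 px, σ_range = 30 levels):
  normalized weighted mean with Gaussian spatial and range kernels. The
  range-kernel argument is the neighbor-minus-center intensity difference,
  the canonical formulation. Radius 0 reduces to the identity; a very large
  σ_range degenerates to a pure spatial Gaussian mean — both limits are
  tested. σ_range = 30 keeps the ~140-level tooth/background step intact
  while smoothing within-region noise.
* **Adaptive binarization** (block 15, offset 0): a pixel is white when it
  exceeds its local block mean minus the offset. The local statistic is the
  plain block mean — the simplest faithful reading of adaptive
  thresholding — with replicated borders. Block 15 is large enough to
  straddle the tooth/gap transition on typical half-tooth crops.
* **Morphology** (3×3 cross, closing then opening): closing first fills
  pinholes inside the white tooth mass, opening then removes isolated
  specks. The order and element are configurable because neither is forced
  by the problem; closing-then-opening is the default since pinholes are the
  dominant artifact after adaptive thresholding. Opening and closing are
  composed set-theoretically — the raster is padded with background before
  the first operation and cropped after the second — so the lattice
  identities (idempotence, anti-extensivity/extensivity) hold exactly even
  for regions touching the border. A note on naming: one sometimes sees the
  dilate-then-erode composition labelled "opening"; this package follows the
  standard convention (opening = erosion then dilation), which matches the
  intended behavior of removing small objects.
* **Canny** (low 50, high 150 on Sobel magnitude): 3×3 Sobel gradient,
  direction-quantized non-maximum suppression, double-threshold hysteresis
  with 8-connected growth. The NMS comparison is strict toward the positive
  gradient direction and non-strict toward the negative, so the two-pixel
  plateau a binary step produces thins to a single-pixel line. No Gaussian
  pre-smoothing is applied — the median and bilateral stages have already
  denoised the crop. The 1:3 low:high ratio is the common heuristic; both
  thresholds are configurable. By default Canny consumes the morphology
  output (the pipeline's arrow order); a config switch redirects it to the
  bilateral output for experimentation on grayscale.
* **Overlay**: the original crop is replicated to three channels and edge
  pixels are painted pure green. Non-edge pixels are bit-identical to the
  original — asserted, not approximated.

## The phantom generator

The generator emulates exactly the structure the chain exploits, with
exhaustive ground truth. Defaults: 600×400 raster, 8 teeth per jaw, tooth
widths 40–60 px, heights 100–140 px, gaps 6–14 px, occlusal band 40 px,
tooth level 200, background 60, Gaussian noise σ = 8, calculus probability
0.3.

* Teeth are exponent-4 superellipses (rounded rectangles) drawn as hard
  masks — no anti-aliasing — so a noiseless phantom contains exactly the
  intensities it was painted with, which makes histogram-level assertions
  exact. Shapes only need to create valley structure in the projections,
  not anatomical realism.
* Tooth/background levels 200/60 place enamel above and background below
  the 170 binarization threshold with ≥ 3σ of headroom at the default noise,
  mirroring the contrast regime the thresholds were designed for.
* The calculus crescent is a bright half-ellipse (body + 40 levels, radii
  0.12 w × 0.30 h) clipped to the tooth footprint at a uniformly chosen
  proximal edge — a bright proximal rim. Clipping matters: a deposit bulging
  into a 6 px gap could fill it and destroy the very valley the segmenter
  must find, whereas real calculus is a subtle edge feature that does not
  erase interdental spacing.
* Noise is additive Gaussian, clipped to [0, 255] and rounded; all
  randomness flows from one seed, and identical specs yield bit-identical
  rasters.

What passing phantom tests does **not** show: robustness to oblique tooth
axes, overlapping crowns, restorations, exposure gradients, or anatomical
texture. The phantom validates the geometry of the algorithms, not their
clinical performance.

## Dataset arithmetic

* **Balancing**: the minority class grows to the target by sampling source
  items with replacement and attaching a random flip/mirror transform
  (hflip, vflip, or both — each an involution); classes above the target are
  subsampled without replacement. The default target `⌊N/2⌋` turns a
  428/912 pool into 670/670. Shrinking the minority below its natural count
  requires explicit consent (`allow_shrink = TRUE`) because it silently
  discards scarce positives.
* **Two-stage split**: `rest = ⌊N(1−holdout)⌋`, `train = ⌊rest·f⌋`,
  `test = rest − train`, `validation = N − rest` — floor on the train share,
  remainders cascading to test then validation. This rule reproduces
  750/322/268 from N = 1340 (holdout 0.2, f = 0.7) and 5/3/2 from N = 10. A
  1e-9 epsilon precedes each floor to guard against binary-fraction
  artifacts (1072 × 0.7 is 750.399…96 in double precision). Setting f = 1
  degenerates to a two-way split (200 → 130/70 at holdout 0.35).
* **Leakage control**: augmented copies are grouped with their root source
  and the shuffled groups are packed into the subsets first-fit against the
  exact quotas, so a transformed duplicate can never sit across the
  train/test boundary from its original. With family sizes small relative
  to the quotas the stated counts are still met exactly; if a family ever
  cannot fit the packer falls back to the subset with the most room.

## Evaluation metrics

Detections are matched greedily in descending confidence, each claiming the
unmatched truth of highest IoU at or above the threshold (default 0.5, the
de-facto convention). Matched detections are Tp, unmatched detections Fp,
unmatched truths Fn; Tn is 0 for detection and only reported when supplied,
because a detector has no natural negative count. Precision, recall
(sensitivity), and specificity are exact ratios reported as percentages; a
zero denominator yields `NA` plus a classed warning, never a silent zero.
AP is the area under the interpolated PR curve using the all-point precision
envelope (an 11-point mode is provided for comparability with older
detection literature), and mAP averages classes, excluding truthless classes
with a warning. mAP is invariant to uniform confidence rescaling, and a
duplicated false positive can never raise it — both are asserted as
properties.

## Numerical choices and degenerate inputs

* All filters round half-up after floating-point accumulation and replicate
  edges; replication avoids the dark halos zero-padding would inject into
  projection profiles.
* Filter outputs stay within `[min(img), max(img)]` and are
  shift-equivariant away from borders — tested properties.
* Erosion/dilation treat everything outside the raster as background; the
  duality `dilate(A)ᶜ = erode(Aᶜ, reflect(B))` therefore holds exactly away
  from the border ring, which is how the tests assert it (a finite raster
  cannot represent the infinite white complement).
* Degenerate parameters fail fast with explicit messages: even kernel
  dimensions, non-positive sigmas, empty structuring elements, infeasible
  phantom geometry, crops too narrow to halve, splits too small for
  non-empty parts.

## Problem sizes in the test suite

The suite validates filters against brute-force double-loop oracles on 100
random 16×16 images (exact for mean/median, ≤ 1 intensity level for the
bilateral), morphology algebra on 50 random 12×12 masks, and segmentation
recovery on 50 seeded phantoms of 6–10 teeth per jaw at noise σ = 10 —
asserting the jaw split within ±5 rows, ≥ 95 % of true gap centers matched
within ±10 columns, and 4 × teeth-per-jaw crops whenever all gaps are found.
These sizes exercise every border case (the oracles dominate the cost; the
compiled filters themselves handle full rasters in milliseconds) while
keeping the default test run fast.
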