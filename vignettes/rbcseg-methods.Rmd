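---
title: "Two-stage erythrocyte segmentation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage erythrocyte segmentation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbcseg)
```

## The problem

Bright-field micrographs of blood smears show erythrocytes (red blood cells,
6–8 µm biconcave discs) as dark rims with a brighter central pallor on a
bright, unevenly illuminated field. Counting cells and measuring their
long/short axis ratio by hand is slow; automating it requires a segmentation
that (a) tolerates noise and illumination gradients, (b) splits cells that
touch, and (c) recovers per-cell shape accurately enough that axis lengths
mean something.

`rbcseg` implements a two-stage procedure. Stage 1 finds and separates
cells globally; stage 2 revisits every cell locally and re-draws its
outline before measuring it.

## Stage 1: global segmentation

The preprocessing chain is fixed, in this order:

1. mean filter, radius 1 (suppresses single-pixel outliers cheaply);
2. rolling-ball background subtraction, radius 100, in light-background
   mode (see below);
3. median filter, radius 4 (removes residual spot noise without moving
   edges);
4. mean filter, radius 3 (final smoothing);
5. linear min–max rescale to 8-bit;
6. bilateral filter, spatial sigma 3 px, range sigma 3 intensity units —
   applied after the rescale so the range sigma reads on the 0–255 scale.

Segmentation then proceeds: Otsu threshold (dark class = cells), hole
filling, disc erosion of radius 2, exact Euclidean distance transform
(inverted so the background is the bright plateau), watershed flooding
with `threshold = 0.004` and `level = 0.4` (fractions of the normalized
relief; `threshold` clips shallow micro-minima, `level` merges adjacent
basins whose dynamic — saddle height minus basin minimum — falls below
it), removal of objects under 25 px, and removal of anything touching the
image border.

Two readings deserve explanation:

* **Light-background rolling ball.** The classical rolling-ball estimate
  (grayscale opening by a spherical-cap element) flattens *bright*
  features on a *dark* field. Erythrocyte images are the opposite, so the
  pipeline inverts the image about the depth maximum, opens, subtracts and
  re-inverts: `out = M - blacktophat(img)`. The background comes out
  uniformly bright with the cells' local contrast preserved.
  `subtract_background()` exposes both polarities; the pipeline default is
  `light_background = TRUE`.

* **The erosion shapes the relief, not the result.** The radius-2 erosion
  exists to sharpen the distance-map basins so the watershed can cut
  touching cells. After flooding, labels are grown back (multi-source BFS,
  nearest label) over the un-eroded, hole-filled Otsu foreground; without
  this the output masks would be systematically 2 px too small and pixel
  sensitivity would drop by several percent on every scene.

## Stage 2: per-cell refinement and morphometry

For each stage-1 object: a rectangular ROI with a 10 px margin; a mask
equal to the object dilated by 6 px *minus the un-dilated pixels of every
other object* in the ROI (neighbours must not leak into the local
histogram); Otsu on the masked pixels only, keeping the darker class;
hole filling; largest 8-connected component. If the masked histogram is
degenerate the cell falls back to its stage-1 shape and is flagged
(`refine_status = "fallback"`); failures never abort the batch, and stage
2 never changes the object count.

Morphometry follows the contour (Moore tracing, clockwise, from the
topmost-then-leftmost boundary pixel):

* **Long axis** — the contour point pair at maximal Euclidean distance,
  computed on the convex hull (every farthest pair is a hull pair) and
  verified in the tests against the all-pairs brute force. Ties break
  lexicographically on the sorted pair.
* **Short axis** — for every Bresenham-rasterized point of the long axis,
  the perpendicular line through it is intersected with the contour:
  points within √2 of the line are candidates; the two mutually farthest
  candidates (if farther apart than `t = 4` px) seed two clusters, the
  rest join the nearer seed, each cluster contributes its point closest to
  the line, and the pair's separation is the score. The best pair over all
  long-axis points is the short axis; exact ties go to the pair crossing
  the long axis nearest its midpoint. When no long-axis point yields a
  valid pair (e.g. a 1-px line) the short axis is reported as absent
  rather than invented.
* **Axis ratio** — short length / long length, in (0, 1]. The
  "width-to-height" ratio of a cell is reported this way because it is
  rotation-invariant, unlike a bounding-box ratio.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `mean_radius_pre` / `mean_radius_post` | 1 / 3 | px | pre/post smoothing windows |
| `median_radius` | 4 | px | spot-noise removal window |
| `ball_radius` | 100 | px | background structuring element |
| `sigma_d`, `sigma_r` | 3, 3 | px, 8-bit intensity | bilateral scales |
| `erosion_radius` | 2 | px | relief sharpening before the distance map |
| watershed `threshold`, `level` | 0.004, 0.4 | fraction of relief range | minima clipping, basin merging |
| `size_threshold` | 25 | px | minimum object area (strict `<` removes) |
| `margin` | 10 | px | ROI padding |
| `mask_dilate_radius` | 6 | px | local mask growth |
| `line_distance_threshold` | √2 | px | short-axis candidate band |
| `pair_distance_threshold` | 4 | px | minimum seed separation |

All of these surface in `pipeline_config()` and in YAML/JSON config files
consumed by the command-line tool.

## Numerical conventions

* Integers are produced by rounding half-up (`floor(x + 0.5)`) everywhere,
  for cross-platform determinism.
* All windowed filters replicate edge pixels; the rolling-ball opening is
  defined as the opening of the replicate-extended image restricted to the
  frame. Binary erosion treats out-of-image pixels as foreground and
  dilation as background, which preserves the opening/closing duality.
* The bilateral window truncates at `ceiling(3 sigma_d)`; on integer-valued
  input the range kernel is an exact lookup table.
* Otsu ties break toward the lowest qualifying threshold; a constant image
  is a degenerate-histogram error (the composed pipeline maps a blank
  image to an empty segmentation instead).
* A min–max rescale of a constant image maps to 0 by convention.
* Coordinates are 0-based `(row, col)`; boxes are half-open.
* Connectivity: 8 for objects, watershed flooding and contour tracing; 4
  for hole-filling background — the standard complementary pairing.
* `remove_small` removes strictly below the threshold (a 24 px object goes,
  a 25 px object stays).

## The exact rolling ball and its fast path

The exact opening by a radius-100 spherical cap costs ~40,000 min/max
operations per pixel — around two minutes per megapixel in optimized
native code, which makes the evaluation protocol (dozens of megapixel-scale
pipeline runs) impractical. `subtract_background()` therefore defaults to
`method = "auto"`: the exact kernel for radii up to 16 px, and for larger
radii a block-minimum shrink (factor 2/4/8 by radius, after a light 3×3
mean that de-biases the minimum under noise), the exact opening with a
proportionally reduced ball on the coarse grid, and bilinear enlargement —
the construction long established in the field's interactive tools. On
smooth backgrounds the coarse estimate differs from the exact one by a
couple of intensity units, which the subsequent min–max rescale and Otsu
threshold absorb; the exact method remains available
(`method = "exact"`) and is what the oracle tests exercise.

## The mock-image generator

`mock_params()` fixes the study conditions; the renderer emulates, in
order: ellipse layout (semi-major axis 14–22 px, eccentricity 1–1.3,
uniform orientation; centres rejection-sampled ≤ 10,000 attempts per
object), two-tone cells (rim 90, interior 140 after a radius-3 erosion —
the interior of a real cell is brighter than its rim), a background that
is brightest (200) at the image centre and falls by up to 30 toward the
corners along a centred Gaussian of scale `0.4 min(h, w)`, Gaussian
smoothing with sigma = radius/2 (radius 3 or 5), and additive zero-mean
Gaussian noise (sd 6, 15 or 30) clipped to 8 bits. Everything is
deterministic given the seed.

Two definitional choices matter:

* `min_gap` is the minimum edge-to-edge separation (3 px by default); a
  negative value permits overlaps up to that depth, for deliberately
  touching pairs.
* `border_margin` (25 px) is measured from the *object edge* to the
  border, not from the centre: the pipeline deletes border-touching
  objects by design, so ground-truth cells must not be border-clipped or
  the evaluation would count those deletions as errors of the method.

What the generator does *not* emulate: leukocytes and platelets, rouleaux
stacking, staining variability, optical vignetting beyond the radial
bump, shot noise (noise here is additive Gaussian, not Poisson), and
sub-pixel edge structure. Passing the synthetic protocol therefore shows
correctness of the pipeline's mechanics under controlled degradation, not
clinical performance on real smears.

The crop/rescale robustness suite emits 5 random crops (side 45–100% of
the source) at scale 1 and at factors 0.7 and 1.3 — 15 scenes — with
bilinear image and nearest-neighbour truth resampling.

## Evaluation

`pixel_metrics()` reports the confusion counts and sensitivity,
specificity, precision, NPV and accuracy; any zero-denominator metric is
`NA` ("undefined"), never silently 0 or 1, so condition sweeps cannot be
corrupted by degenerate scenes. Object-level agreement is deliberately a
count comparison only — the protocol this package reproduces evaluates
pixel metrics and counts, not per-object IoU.

Problem sizes used by the test suite, chosen to keep a full run in the
tens of minutes on one core: the reference evaluation scenes are
1024×1024 with 124 cells; the noise-trend sweep uses 512×512 with 31
cells (the same cell density); module tests use fixtures from 3×3 up to
~200×200.

## Known limitations and observed behavior

* With the generator's contrast settings, the global Otsu threshold sits
  partway up the blurred edge ramp (the background mode is much tighter
  than the broad cell class), so stage-1 masks run 1–3 px wide. This is
  precisely the behavior the per-cell second stage corrects — the test
  suite checks that full-pipeline precision exceeds the stage-1 value on
  the hardest degradation — but it also means cells placed at the minimum
  3 px gap can fuse, and a fused pair whose smaller member has a watershed
  dynamic below the level 0.4 stays merged. A few such pairs per
  124-cell scene are typical; the object count then lands just under the
  truth.
* The dynamics-based merge rule makes knife-edge cases (dynamic exactly at
  the level) resolve by discretization; the two-disc split test uses a
  configuration comfortably above the level for that reason.
* 16-bit output is TIFF-only (no installed encoder writes 16-bit PNG).
* The short-axis procedure measures chords between rasterized contour
  points; on shapes a few pixels across the ±1 px discretization is a
  large relative error, so axis ratios of objects near the 25 px size
  floor should be treated with caution.
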