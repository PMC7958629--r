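# rbcseg

Two-stage segmentation and morphometry of erythrocytes (red blood cells)
in bright-field microscope images.

Blood-smear micrographs show erythrocytes as dark rims with a brighter
central pallor on a bright, unevenly illuminated field. Counting cells and
measuring their shape by hand is slow and imprecise. `rbcseg` automates
it: it separates even touching cells, draws a refined outline for each
one, and reports per-cell size, long/short axis lengths and the axis
ratio.

## Method

**Stage 1 (global).** The image is denoised and flattened — mean filter
(r = 1), rolling-ball background subtraction (r = 100, light-background
mode), median filter (r = 4), mean filter (r = 3), 8-bit rescale,
bilateral filter (σ_d = σ_r = 3) — then binarized with Otsu's threshold
(the cut `t*` maximizing the between-class variance
σ²_B(t) = ω₀ω₁(μ₀ − μ₁)²; cells are the darker class). After hole filling
and a radius-2 erosion, the inverted Euclidean distance transform
`D_max − D` is flooded by a watershed (threshold 0.004, level 0.4 as
fractions of the normalized relief; basins with dynamic below the level
merge), which places dams where touching cells meet. Objects under 25 px
and objects touching the border are discarded.

**Stage 2 (per cell).** Each object gets a 10 px-margin ROI and a local
mask (own pixels dilated by 6 px, minus any neighbour's pixels). Otsu is
re-run on the masked pixels only; the darker class is kept, holes are
filled, the largest component survives. From the Moore-traced contour the
**long axis** is the point pair at maximal Euclidean distance; the
**short axis** is the longest contour-to-contour chord perpendicular to
it, found by the perpendicular-line cross-point clustering procedure
(candidates within √2 of the line, seed pair > 4 px apart). The axis
ratio is short/long.

The package also ships a parametric generator of ground-truthed artificial
blood-smear images (two-tone cells, centrally brightened background,
Gaussian smoothing, additive noise) and a pixel-level evaluation harness
(sensitivity, specificity, precision, NPV, accuracy, object counts), so
the whole pipeline can be validated quantitatively without annotated data.
See the methods vignette (`vignettes/rbcseg-methods.Rmd`) for the design
rationale.

## Worked example

```r
library(rbcseg)

params <- mock_params(height = 320, width = 320, n_objects = 8,
                      border_margin = 30, seed = 7)
scene <- mock_scene(params)            # image + ground truth
res <- segment_image(scene$image)      # full two-stage pipeline
head(res$measurements[, c("label", "area_px", "long_len", "short_len",
                          "axis_ratio", "refine_status")], 4)
#>   label area_px long_len short_len axis_ratio refine_status
#> 1     1    1439 44.91102  39.81206  0.8864652       refined
#> 2     2    1252 41.23106  37.01351  0.8977095       refined
#> 3     3    1261 42.20190  37.20215  0.8815279       refined
#> 4     4    1260 41.77320  37.85499  0.9062028       refined

evaluate_run(scene, stage = "full")
#> <eval_report>
#>   tp 8267  fp 608  tn 93525  fn 0
#>   sensitivity  1.0000
#>   specificity  0.9935
#>   precision    0.9315
#>   npv          1.0000
#>   accuracy     0.9941
#>   objects: 8 detected / 8 truth
```

All 8 synthetic cells are found; every pixel of every true cell is
recovered (sensitivity 1.0) with a thin halo of false foreground around
the blurred edges (precision 0.93); each cell's axis ratio is close to
its drawn eccentricity.

## Command line

A thin wrapper over the same functions lives at
`inst/cli/rbcseg` (after installation:
`system.file("cli", "rbcseg", package = "rbcseg")`):

```sh
rbcseg mock     --out scene/ --seed 7                 # scene + ground truth
rbcseg segment  --input scene/image.png --out seg/    # labels, overlay, CSV
rbcseg evaluate --pred seg/labels.tif --truth scene/truth_labels.tif \
                --out report.json
rbcseg evaluate --sweep --out sweep.csv               # smoothing x noise grid
```

Overlays draw contours red, long axes blue, short axes green. All
parameters can be overridden from a YAML or JSON config
(`--config file.yaml`); exit codes are 0 (ok), 1 (I/O), 2 (config),
3 (processing).

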