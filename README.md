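# shallotvision

Machine-vision yield monitoring for shallot onions on a harvester conveyor.

Shallots are harvested by a conveyor windrower, and their market class is set
by bulb diameter. A camera mounted over the belt can count bulbs and grade
them by size *during* harvest, turning every frame into a geotagged yield
record. `shallotvision` implements that monitor as a tested R library with a
command-line interface, for agricultural engineers and image-analysis
researchers working on specialty-crop yield mapping.

## What it computes

**Segmentation.** Each RGB frame is median- then Gaussian-blurred (9 × 9,
σ = 1.7), converted to HSV, and thresholded to the bulb-skin hue bands
H ∈ [0, 40] ∪ [160, 180] plus a specular band (H ∈ [0, 60], S ∈ [240, 255]),
on the 0–180 / 0–255 scales. After opening and closing with a 12 px circular
element, the exact Euclidean distance transform D(x) of the mask is computed;
its local maxima (minimum separation 20 px) seed a marker-controlled
watershed that floods −D(x), so touching bulbs split at the ridge between
their distance peaks. Each surviving region is measured by the minimum
enclosing circle of its contour.

**Sizing.** A reference ball of known diameter T_d is color-segmented and
located with a Circle Hough Transform, giving the pixel metric

    Pm = Pd / Td        [pixels per mm]

Bulb diameters convert as d_mm = d_px / Pm and are graded by half-open
intervals: small (d < 44 mm), medium (44 ≤ d < 54), large (d ≥ 54), the cuts
being the midpoints of adjacent-class extremes in a hand-calipered grading
sample and re-derivable from any labelled sample with `derive_thresholds()`.

**Mapping and evaluation.** NMEA 0183 (GGA/RMC) fixes are attached to frames
by nearest timestamp (≤ 2 s), and per-frame class counts export to CSV and
GeoJSON. Detections are scored by greedy one-to-one centroid matching
(precision = TP/(TP+FP), recall = TP/(TP+FN)), diameters by RMSE, SD, SEM,
and per class by the two-sample Kolmogorov–Smirnov statistic
D = sup_x |F̂₁(x) − F̂₂(x)| with asymptotic two-sided p-values.

A seeded synthetic-scene generator renders conveyor-like frames with exact
ground truth (bulb centers, diameters, classes, occlusion flags, optional
calibration ball, simulated GPS track), so the whole chain is testable with
no field data.

## A worked example

```r
library(shallotvision)

scene <- generate_scene(scene_spec(n_bulbs = 5, seed = 42))   # 640 x 480 at 3.38 px/mm
cfg   <- run_config(pixel_metric = pixel_metric(3.38, 1))
bulbs <- detect_bulbs(scene$frame, cfg)
bulbs[, c("centroid_row", "centroid_col", "diameter_px", "diameter_mm", "size_class")]
#> # A tibble: 5 × 5
#>   centroid_row centroid_col diameter_px diameter_mm size_class
#>          <dbl>        <dbl>       <dbl>       <dbl> <fct>
#> 1        317.          168.        172.        50.8 medium
#> 2         86.5         271.        160.        47.3 medium
#> 3        409.          389.        139.        41.2 small
#> 4        110.          447.        131.        38.7 small
#> 5        350.          573.        134.        39.8 small
```

All five bulbs are found where the generator placed them, converted to
millimetres by the configured 3.38 px/mm metric, and graded. Matching the
detections to the scene's ground truth:

```r
conf <- match_detections(
  data.frame(row = bulbs$centroid_row, col = bulbs$centroid_col),
  data.frame(row = scene$truth$row, col = scene$truth$col),
  max_dist = 0.5 * mean(scene$truth$diameter_px))
tidy(conf)
#> # A tibble: 1 × 6
#>      tp    fp    fn    tn precision recall
#> 1     5     0     0     0         1      1

ks_two_sample(bulbs$diameter_mm, scene$truth$diameter_mm)
#> Two-sample KS test: D = 0.6000, p = 0.3291 (n1 = 5, n2 = 5)
#> H0 (same distribution) not rejected at alpha = 0.05
```

Detection is perfect on this clean scene (precision and recall 1); the KS
test compares the predicted and true diameter distributions and finds no
significant difference at α = 0.05. `plot_detections(scene$frame, bulbs)`
draws the class-colored circle overlays (blue = small, green = medium,
red = large).

The same pipeline is scriptable from a shell via `inst/cli/shallotvision`
with `calibrate`, `detect`, `evaluate` and `simulate` subcommands (exit
codes: 0 success, 1 empty input, 2 I/O or validation failure).

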