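# spikeobb

Oriented bounding-box tools for detecting and counting elongated crop
organs — sorghum spikes in particular — in UAV imagery.

## The problem

Sorghum spikes photographed from a drone at ~10 m are small (long sides
generally under 100 px), slender, dense, and oriented every which way.
Axis-aligned detection boxes merge neighbours and carry no orientation, so
oriented-detection pipelines describe each spike as an **oriented box**
`(cx, cy, w, h, θ, cls)` with `θ` the angle of the long side against the
x-axis, folded to `[0°, 180°)` with `w ≥ h`. This package implements the
computational core such a pipeline needs, independent of any trained
network or field dataset:

- **Rotated-box geometry** — the intersection of two oriented boxes is a
  convex polygon (triangle up to octagon) found by Sutherland–Hodgman
  clipping; its area is the sum of fan triangles, equal to the shoelace
  value. On top of it: exact rotated IoU and the overlap-to-area-sum ratio
  `|A∩B| / (|A|+|B|) ∈ [0, 0.5]`.
- **Circular smooth labels (CSL)** — the angle as a 180-category
  classification target, `CSL(x) = exp(−d(x,θ)²/2σ²)` inside a window of
  radius `r` around `θ` (wrapping at the 0/180 boundary) and 0 outside,
  with periodic angle distance `d`.
- **Wise-IoU loss** — `L = Σ α·(1−IoU)` with the focusing factor
  `α = exp(((GTx−Bx)² + (GTy−By)²) / (GTw+GTh)²)`, forward evaluation for
  assigned pairs.
- **Oriented NMS** — greedy score-descending duplicate removal keyed by the
  sum-of-areas overlap ratio (default threshold 0.25).
- **Evaluation** — greedy rotated-IoU matching; mAP by all-points
  interpolated precision–recall integration; pooled angle errors RMSEa/MAEa
  (circular difference); per-image count errors RMSE/MAE.
- **Data plumbing** — roLabelImg XML and DOTA-style text annotations,
  PNG images, 600 px tiling with annotation clipping, the
  rotate/flip/brightness augmentation suite (10 outputs per input), and
  6:1:3 dataset splitting.
- **Synthetic scenes** — seeded generator emulating field statistics
  (≈30 spikes/image, sub-100 px, angles concentrated at 0°) plus a
  perturbation harness and a rasterization oracle, so everything above is
  testable offline.
- **Reference DCSA operators** — forward-pass deformable convolution
  (bilinear sampling, offsets as inputs) and scaled dot-product attention
  `softmax(QKᵀ/√d)·V`, for verifying operator semantics. No training.

Everything is tidyverse-shaped: boxes are tibbles, verbs pipe, results have
`tidy()` / `glance()` / `autoplot()` methods.

## A worked example

Generate a ground-truth scene, simulate a noisy detector, suppress
duplicates, and evaluate:

```r
library(spikeobb)
library(dplyr)

gt <- generate_annotations(seed = 1, image_id = "demo") # 26 spikes
det <- perturb_annotations(gt,
  angle_sd = 10, center_sd = 2, p_miss = 0.1,
  fp_rate = 3, seed = 2
) # 30 scored detections
det <- oriented_nms(det)
ev <- evaluate_detections(
  mutate(det, image_id = "demo"),
  mutate(gt$boxes, image_id = "demo"),
  iou_threshold = 0.3
)
ev
#> Oriented detection evaluation (1 image(s))
#>   mAP 0.9586 | RMSEa 10.604 deg | MAEa 8.734 deg | count RMSE 4.000 | MAE 4.000
#>   matched 25 | IoU threshold 0.30 | score threshold 0.00
```

Read: with 10° of injected angle noise the recovered RMSEa is ≈10.6°
(the estimator tracks the noise actually present); 25 of 26 spikes were
matched, and the 4-count error comes from misses plus surviving false
positives at this operating point. Individual primitives are just as
direct:

```r
rotated_iou(oriented_box(100, 50, 80, 20, 30),
            oriented_box(110, 55, 80, 20, 40))
#> [1] 0.5713983

round(csl_encode(45)[42:50], 4) # Gaussian window around bin 45
#> [1] 0.1353 0.3247 0.6065 0.8825 1.0000 0.8825 0.6065 0.3247 0.1353
```

A command-line driver wraps the same functions
(`Rscript inst/cli/spikeobb.R <synth|augment|tile|convert|nms|evaluate|demo> --flags`),
logging its seed and config hash and writing JSON reports.

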