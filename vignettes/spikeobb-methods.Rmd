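---
title: "Oriented-box methods for spike detection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oriented-box methods for spike detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikeobb)
library(dplyr)
```

## The problem

Sorghum spikes seen from a UAV at around 10 m altitude are small (long sides
generally under 100 px at ~0.4 cm/px), slender, densely packed, and lie at
essentially arbitrary orientations. Axis-aligned detection boxes fit them
poorly: they merge neighbours, admit large amounts of background, and carry
no orientation signal. The remedy is the *oriented* bounding box — center
$(c_x, c_y)$, side lengths $(w, h)$ and a long-side angle $\theta$ — plus a
set of supporting components this package implements as reusable,
dataset-free primitives:

* exact rotated-box overlap by convex polygon clipping with triangulated
  areas;
* circular smooth label (CSL) encoding of the angle into 180 one-degree
  categories;
* a Wise-IoU localization loss for assigned prediction/truth pairs;
* oriented non-maximum suppression driven by the overlap-to-area-sum ratio;
* detection, angle and count evaluation metrics (mAP, RMSEa, MAEa, RMSE,
  MAE);
* annotation-aware augmentation and tiling, with roLabelImg-XML and
  DOTA-text I/O;
* a synthetic scene generator so all of the above is testable end to end.

Training a detector is out of scope throughout: the two network operators
that are included (deformable convolution sampling and scaled dot-product
attention) are *reference forward passes* for verifying operator semantics,
with offsets supplied as inputs.

## Box model and angle conventions

All coordinates are continuous pixels with the origin at the image's
top-left corner, x to the right and y downward; geometry is computed in
this stored frame throughout, so every module agrees on what an angle
means. The angle is that of the box's **long** side against the x-axis.
Under this convention a box is invariant under $\theta \mapsto \theta +
180^\circ$, so normalized boxes satisfy $w \ge h$ and $\theta \in [0,
180)$; when an input has $w < h$ the sides are swapped and $90^\circ$
added. The 180-category CSL head fixes this range: one category per degree
requires exactly the $[0, 180)$ fold.

Degenerate boxes ($w \le 0$ or $h \le 0$) are rejected rather than treated
as segments — every downstream quantity (IoU, the loss normalizer) would
otherwise divide by zero area.

## Rotated overlap by clipping and triangle sums

The intersection of two rectangles at arbitrary angles is a convex polygon
with between 3 and 8 vertices. `convex_intersection()` computes it by
Sutherland–Hodgman clipping of one rectangle against each edge of the
other, and `polygon_area()` measures it by fan triangulation from the first
vertex — splitting the region into triangles that share a vertex and
summing their areas — which for a convex polygon equals the shoelace value
to floating point (both methods are exposed and the test suite asserts
their agreement to 1e-9 relative on every random intersection it
generates). Two ratios are built on this area:

* `rotated_iou()` — area of intersection over union, the matching score
  used by the evaluator;
* `overlap_ratio_sum()` — intersection over the *sum* of the two areas,
  which ranges over $[0, 0.5]$ with 0.5 exactly at coincidence. This is
  the duplicate-removal criterion.

Numerical choices: vertices closer than 1e-9 px are merged; clipping
decisions use a 1e-9 tolerance on cross products; touching contact (a
shared edge or corner) therefore counts as zero overlap, which is the
behaviour one wants when adjacent spikes abut. Correctness is checked
against an independent rasterization oracle (`rasterized_iou_oracle()`,
point-in-rectangle counting on a 2000-square grid, no clipping code
shared) over hundreds of random pairs, and against closed forms such as the
square-vs-45°-rotated-square octagon, whose IoU is exactly $1/\sqrt 2$.

## Circular smooth labels

Treating each integer degree as a category turns angle regression into
classification, but a plain one-hot label would penalize a 179° prediction
of a 1° truth as badly as a 90° one. The CSL vector instead places a
Gaussian window around the true angle on the **angle circle** of period
180:

$$\mathrm{CSL}(x) = \begin{cases} g(x) & \theta - r < x < \theta + r \\ 0 &
\text{otherwise} \end{cases}, \qquad g(x) = \exp\!\left(-\frac{d(x,
\theta)^2}{2\sigma^2}\right)$$

with $d$ the circular angle distance and the window wrapping across the
0/180 boundary. Parameter defaults are package choices: $r = 6^\circ$
(consistent with the CSL literature's working range) and $\sigma = r/3$,
which places the window edge at three standard deviations; both are
arguments. The peak is normalized to 1 — the vector is a label, not a
density. Decoding is argmax with ties to the smallest index; expectation
decoding was considered and rejected because the windowed vector is not a
distribution and argmax makes the integer round-trip exact, which the test
suite asserts for all 180 integer angles at several radii. Sub-degree
angles are encoded about their real value and decode to the nearest degree
(quantization error at most 0.5°).

`circular_angle_distance()` — $\min(|a-b| \bmod 180,\ 180 - |a-b| \bmod
180)$ — is also the angle-error measure in evaluation, so a 179°-vs-1°
disagreement counts 2°, not 178°; the raw difference remains available
behind a flag for comparability with conventions that ignore the wrap.

## Wise-IoU loss

For assigned pairs the localization loss is

$$L_{WIoU} = \alpha \cdot L_{IoU}, \qquad L_{IoU} = \sum_i (1 -
\mathrm{IoU}_i), \qquad \alpha = \exp\!\left(\frac{(GT_x - B_x)^2 + (GT_y -
B_y)^2}{(GT_w + GT_h)^2}\right)$$

where the normalizer uses the ground-truth sides exactly as written (not
the detached or batch-mean forms of other Wise-IoU variants). The
assignment is the pair list itself; no anchor strategy is implemented, and
the loss is forward-only — it exists to inspect and verify the formula, not
to train. The IoU inside the loss defaults to the *horizontal*
(axis-aligned) IoU of the decoupled representation, in which orientation is
carried by the CSL classification branch and the regression target is
$(x, y, w, h)$ alone; rotated IoU is selectable. Useful identities the
tests exploit: $\alpha \ge 1$ with equality iff centers coincide, so the
Wise-IoU total never falls below the plain IoU loss; both $\alpha$ and IoU
are ratios, so the loss is invariant under common translation and global
scaling.

## Oriented NMS

Duplicate removal is greedy score-descending suppression: keep the
highest-scoring box, discard any remaining box whose overlap criterion with
a kept box exceeds the threshold, repeat. The criterion is the
overlap-to-area-sum ratio with default threshold 0.25 — the midpoint of the
ratio's $[0, 0.5]$ range, playing the role IoU 0.5 plays in conventional
NMS; plain IoU is available as an alternative criterion. A literal "keep
the box with the highest overlap ratio" rule was considered and rejected:
isolated detections overlap nothing and would all be discarded, which
contradicts the purpose of removing duplicates while keeping one box per
spike. Ties in score break by input order under a stable sort, making the
kept set invariant to input permutation; suppression is idempotent and
keeps weakly more boxes as the threshold rises.

## Evaluation metrics

Matching is greedy in score order: each prediction takes the unmatched
ground truth of highest rotated IoU provided it reaches the threshold
(default 0.5, configurable). Matched pairs are TP; leftovers are FP and FN.
From the pooled detections the precision–recall curve is built
cumulatively, and average precision integrates the monotone (all-points
interpolated) precision envelope over recall — with one class, mAP equals
this AP. The 11-point variant is available for comparability with older
protocols.

Angle errors (RMSEa/MAEa) pool **matched pairs across all images** rather
than averaging per image: the printed per-image indexing is ambiguous when
images contain different spike counts, and pooling weights every spike
equally; the per-image-mean alternative can be recovered from the match
objects. False positives and negatives affect mAP and counts, never the
angle metrics. Count errors (RMSE/MAE) are per-image differences between
labeled and predicted counts; the evaluator takes an explicit score
threshold so the counting operating point is always stated. Evaluating any
ground truth against itself yields mAP 1 and zero errors exactly, and
injected wrapped-Gaussian angle noise of known σ is recovered as RMSEa ≈ σ
— both are standing tests.

## Augmentation and splitting

The augmentation suite emits, per input image: rotations by 90°, 180° and
270°, horizontal and vertical flips, and brightness factors 0.8, 0.9, 1.1
and 1.2 — with the original retained by default, ten outputs per input, so
600 annotated images become 6000. Augmentations apply to originals only (no
stacking), the minimal reading consistent with that tenfold factor.
Annotations transform exactly: a quarter turn maps $(c_x, c_y) \mapsto (H -
c_y, c_x)$ with $\theta \mapsto \theta + 90$; either flip maps $\theta
\mapsto 180 - \theta$; the flip mirror is about the continuous extent $W$
(not $W - 1$), matching the continuous box model. Brightness scales pixels
with clipping to $[0, 255]$ and never touches annotations.

`split_dataset()` partitions at 6:1:3 by default with largest-remainder
rounding under a seeded shuffle. The split applies to the list as given —
typically *after* augmentation, so augmented variants of one original can
straddle splits; when that leakage matters, split the originals first and
augment each part.

## Tiling and file formats

Large frames are tiled on a stride-equal grid with the final row and column
anchored to the image edge, so a 4032×2268 frame yields 7×4 tiles of
600 px. A box belongs to a tile if at least half its area lies inside (ties
to the lower tile index, scanning row-major), is clipped to the tile, and
is re-fit as the smallest enclosing rotated rectangle **that stays within
the tile**: the unconstrained minimum-area rectangle of a clipped polygon
can overshoot the cut line, so candidate orientations (from the convex
hull's edges, rotating-calipers style) are admitted only when contained,
with the axis-aligned bounding box as the always-valid fallback. The
half-area rule and edge anchoring are package decisions; only the 600 px
tile size is a field convention.

roLabelImg XML stores each box as center/sides/angle with the angle in
radians; reading converts to degrees and normalizes, so the only lossy step
is the documented 180° fold. DOTA-style text stores the four corner
coordinates plus class and either difficulty (ground truth) or score
(detections); corners are converted back to a box via the minimum-area
enclosing rotated rectangle, and both formats round-trip to better than
1e-6 px. Images are read and written as PNG.

## The synthetic generator

`generate_annotations()` draws a spike count (Poisson with mean 30 by
default — the typical per-image count in field data), long sides uniform on
40–95 px (the under-100 px small-object regime), aspect ratios 0.2–0.45
(slender targets), and angles from a mixture chosen as a stylized match to
annotated field distributions: 45% wrapped-normal at 0° (sd 10°), 15% at
90° (sd 10°), 40% uniform — concentrated at 0° with a secondary mode at
90°. Boxes are placed by rejection so no pair overlaps beyond a
sum-of-areas ratio of 0.05, keeping distinct spikes well below the NMS
threshold. `generate_scene()` renders each spike as a textured filled
ellipse inscribed in its exact ground-truth rectangle on a noisy
canopy-like background.

What the generator deliberately does **not** emulate: real canopy texture,
occlusion and intertwined spikes, growth-stage color variation, perspective
and blur. Tests passing on these scenes therefore validate the *geometry,
label, suppression and metric machinery* — they say nothing about detector
accuracy on real imagery, which requires a trained network and a real
dataset and is out of scope. `perturb_annotations()` closes the loop for
the evaluator: misses, false positives, and Gaussian noise on centers,
sizes and (wrapped) angles, with true-detection scores from Beta(8, 2) and
false-positive scores from Beta(2, 5) so precision–recall curves are
non-trivial.

Every generator accepts a seed and is exactly reproducible under it; all
randomness is local to the call (`withr::with_seed`), leaving the caller's
RNG state untouched.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script study sizes are package choices
balancing statistical resolution against a desk-scale run: 500 random box
pairs against the 2000-square rasterization oracle (tolerance 0.01);
angle-noise recovery pooled over ≥ 3000 matched boxes from 110
Poisson(30) scenes (RMSEa within 5% of the injected 10°); NMS count
recovery over 100 scenes of jittered duplicate triplets; the augmentation
factor demonstrated on 600 small rendered scenes; and a 40-scene
end-to-end noisy study. The oracle comparison uses a reduced 200-pair /
1000-grid sweep in the acceptance script, where it is a reported quantity
rather than a tolerance gate.

## Known limitations

* Geometry is exact but scalar-looped; for millions of pairwise overlaps a
  vectorized or compiled kernel would be preferable.
* The loss is forward-only (no gradients), and the DCSA operators are
  reference implementations — offsets are never predicted, and the
  micro-scale detection branch and backbone wiring of a full detector are
  intentionally absent.
* Multi-class evaluation beyond the single "spike" class is limited to the
  trivial case (mAP equals the one class's AP).
* Angle decoding is integer-degree; sub-degree precision would need a
  different head.

## A worked example

```{r example}
gt <- generate_annotations(seed = 1, image_id = "demo")
det <- perturb_annotations(gt,
  angle_sd = 10, center_sd = 2, p_miss = 0.1,
  fp_rate = 3, seed = 2
)
det <- oriented_nms(det)
ev <- evaluate_detections(
  mutate(det, image_id = "demo"),
  mutate(gt$boxes, image_id = "demo"),
  iou_threshold = 0.3
)
glance(ev)
```

The report object also offers `tidy()` (per-image counts) and `autoplot()`
(the precision–recall curve); annotated scenes plot with `autoplot()` as
well.
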