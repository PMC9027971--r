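---
title: "Multi-stage 2D surgical planning: models, encodings and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-stage 2D surgical planning: models, encodings and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(kneeplanr)
```

kneeplanr implements a three-stage pipeline for (semi-)automatic surgical
planning of knee ligament reconstruction on lateral radiographs:

* **Stage A** — a multi-task hourglass network detects all anatomical
  features of a planning application in parallel, each in a spatial
  encoding suited to its type: multi-label segmentation masks for bones,
  Gaussian heatmaps for keypoints, line-symmetric heatmaps for elongated
  structures.
* **Stage B** — the spatial encodings are decoded into geometric objects:
  sub-pixel keypoints (argmax or least-squares Gaussian fit), smooth
  polylines (thresholded weighted point cloud + parametric smoothing
  splines), closed polygons (component tracing), and weighted contour
  subsections.
* **Stage C** — a parameterized, ordered blueprint interrelates the named
  features into the surgical plan (drill points, guidewires). Because
  Stage C is a cheap pure function of the features, the user can edit any
  feature and the whole plan is recomputed in real time.

This vignette records the modeling assumptions, parameter meanings and the
design decisions taken where the problem left genuine freedom. Every
empirical statement here is one the package's test-suite or acceptance
script computes itself.

## Coordinate conventions

All geometry uses 0-based continuous coordinates, x rightwards, y
downwards, origin at the **center** of the top-left pixel; the image
domain is the half-open box `[0, W) x [0, H)`. Angles are in degrees from
the +x axis; a positive rotation applies the standard mathematical
rotation matrix to the raw `(x, y)` coordinates (so +90 degrees maps
`(10, 0)` to `(0, 10)`); undirected line orientations are reported in
`(-90, 90]`. Pixel-to-mm calibration comes from a reference sphere of
known diameter (30 mm by default): `mm_per_px = d_mm / d_px`.

## Spatial encodings

Keypoints are encoded as unnormalized bivariate Gaussians with standard
deviation `sigma` (default 6 px): the value at the keypoint coordinate is
exactly 1. Lines are encoded by the same Gaussian applied to the distance
to the nearest point of the polyline, inside a hull of orthogonal width
`6 sigma`. Both encodings are truncated at `3 sigma`: values at distance
`<= 3 sigma` are kept (boundary inclusive — the choice is immaterial to
learning but fixed so tests can be exact), everything beyond is exactly
zero. The hull is capped past segment endpoints by round caps (the
distance-to-segment metric); a flat cap would make the field
discontinuous at the endpoints.

Segmentation ground truth is **multi-label**: one binary channel per
structure, overlap permitted, because transmissive imaging superimposes
structures additively; a pixel belongs to every bone whose projection
covers it. Rasterization sets a pixel iff its center lies inside the
polygon (even-odd rule, holes subtracted).

Thresholds quoted in sigma units are mapped to likelihood values through
the unit-peak Gaussian: the "1 sigma" point-selection threshold used in
line decoding is `exp(-0.5) ~ 0.6065`, the "2 sigma" truncation used by
the moment metrics is `exp(-2) ~ 0.1353`. This is the only reading
consistent with unit-peak encodings.

## The network and its training protocol

The detector is a single hourglass: a contracting path of residual
pre-activation bottleneck blocks (BN - ReLU - 1x1, BN - ReLU - 3x3,
BN - ReLU - 1x1 with a halved bottleneck width, plus identity shortcut),
max-pooled between levels; an expanding path with nearest-neighbour
upsampling; and **parameterized skip connections** (a bottleneck on each
skip path). The channel count is constant across all scales (default 128)
— all abstraction levels get equal capacity, unlike the doubling scheme
of U-Nets. Three parameter-sharing topologies are available:

* `single_task`: one full encoder-decoder and head per task (no sharing);
* `multi_head`: encoder **and** decoder shared, per-task 1x1 heads;
* `multi_decoder`: shared encoder, per-task decoders and heads.

Trainable-parameter counts order as
`multi_head < multi_decoder < sum of single_task`, which the tests assert
by construction. Segmentation heads are per-channel sigmoids (multi-label,
not a softmax partition); heatmap heads are linear, trained with MSE, and
clamped to `[0, 1]` only at decoding.

Training follows a fixed protocol: mini-batches of 2, Nesterov momentum
with a triangular cyclical schedule (learning rate 0.001 to 0.1 and back
over a full cycle of 360 update iterations; momentum annealed inversely
between 0.9 and 0.8 — the phase relation is a convention we fix, with
momentum high when the learning rate is low), L2 weight decay 5e-5 on
convolution weights, and online augmentation applied in **coordinate
space**: shear in [-2, 2] degrees (p = 0.5), horizontal flip (p = 0.5),
rotation in [-45, 45] degrees (p = 1), scale in [0.8, 1.2] (p = 1).
Images are warped bicubically; ground-truth geometry is mapped by the
exact same affine and re-encoded afterwards, so labels never pass through
raster interpolation. An alternative `rmsprop_step` optimizer (learning
rate 0.001 with a single x0.1 decay at epoch 350) mirrors the protocol
used for intra-operative data, where the cyclic policy can be unstable.
If an augmented keypoint leaves the frame its target channel is all-zero
for that draw (an invisible landmark); at the raw encoding stage, by
contrast, encoding an out-of-domain keypoint is an error, because there
it indicates a labeling bug.

Losses: segmentation uses Soft-Dice + BCE, each averaged over channels
(Soft-Dice smoothing of +1 in numerator and denominator); keypoints and
lines use plain MSE over all pixels. The composite objective is the
weighted sum over tasks. Model selection minimizes the **unweighted**
composite validation loss after each epoch — selection is deliberately
independent of the weighting policy.

### Task weighting

Uniform weighting sets all weights to 1. GradNorm balances the per-task
training rates: with `G_t` the gradient norm of the weighted task loss at
the last shared layer (we designate the shared neck convolution for
`multi_head` and the bottom bottleneck's closing convolution for
`multi_decoder` — the layer closest to where the paths separate), and
`r_t` the relative inverse training rate, one gradient step is taken on
`sum_t |G_t - mean(G) r_t^alpha|` (asymmetry `alpha = 1`), after which
weights are renormalized to sum to the number of tasks and clamped
positive. Reference losses for `r_t` are recorded after the first
optimization step (dividing by an untrained first-forward loss is
noise-dominated); this is config-exposed. The weight step uses a small
fixed step size (0.025, the conventional choice for GradNorm) rather than
the cyclic schedule: weight updates ride on a renormalized simplex where
the 100x learning-rate sweep of the cyclic policy has no useful
interpretation.

## Stage B decisions

* Argmax decoding breaks ties deterministically (lowest y, then lowest
  x) and treats peaks below a floor (default 0.05) as "not detected" — a
  typed result, not an exception, so Stage C can cancel gracefully.
* The Gaussian least-squares decoder fits amplitude, center and sigma on
  a window of radius `3 sigma` around the argmax and falls back to the
  argmax if the fit diverges or drifts beyond the window. Whether the
  paper-style pipeline applies the fit always or adaptively is left as a
  per-feature configuration; the default is argmax.
* Line decoding orders the above-threshold points by projection onto the
  cloud's principal axis before spline fitting. Curved lines that double
  back along their principal axis are out of scope (no knee planning line
  does). Splines are parametric cubic smoothing splines in arc length;
  vertical lines are unproblematic because nothing is ever expressed as
  `y = f(x)`.
* Contour extraction keeps the largest connected component per channel,
  drops components below 1% of the largest, and flags fragmentation
  (two or more surviving components) — the known intra-operative failure
  mode that downstream planning treats as grounds for cancellation. The
  traced pixel-center ring is offset outward by half a pixel (mitered
  normals) so enclosed areas match the pixel-count convention.

## Stage C blueprints

Construction constants (quadrant fractions, AP-diameter fractions, mm
offsets, wire angle) are mandatory blueprint configuration with defaults
drawn from the cited clinical planning literature; they are
**non-normative** and must be reviewed per deployment. Feature identity
is a configurable registry: the package does not hard-code which
clinical landmark each label denotes beyond the phantom's own
definitions (`K1`/`K2` Blumensaat endpoints, `K4`/`K5` tibial AP plateau
endpoints, `K6` posterior facet, `K3`/`K7` distal femoral surface points,
`L2` posterior cortex, `L3` tibial shaft axis).

The cortex extension line is fitted by total least squares (orthogonal
regression) — stable for near-vertical lines, where ordinary regression
on `y = f(x)` degenerates. "Anterior" for the Schoettle-type offset is
resolved as the side of the cortex line containing the two keypoints'
centroid. The PCL plan refuses to run uncalibrated (its constants are
metric); the shaft-axis direction is oriented distally (+y). Every plan
op is similarity-equivariant, checked against independently transformed
oracles on randomized instances, and returns a `cancelled(reason)` status
instead of crashing whenever an input feature is missing or degenerate.

## The phantom generator

Clinical cohorts cannot be redistributed, so all training and evaluation
runs on synthetic lateral knee phantoms with exact analytic ground truth.
The phantom is schematic, not anatomically realistic: what matters to
Stages A-C is structural — smooth bone outlines with landmarks **on**
them, femorotibial overlap under additive intensities, a visible oblique
intercondylar ridge, shaft truncation by the field of view, implant-like
high-intensity overlays, bilateral exposure, and a stored mm-per-px scale
(drawn uniformly from [0.2, 0.5], emulating the calibration-sphere
pathway). The femur is a condyle disc merged with a shaft capsule, the
tibia a plateau block with a shaft; every sample is deterministic in
`(seed, index)`.

Two structures are rendered in the image but deliberately not annotated:
a fibula-like capsule posterior to the tibial shaft and a patella-like
ellipse anterior to the condyle. They give the phantom the chirality of a
real lateral projection. Without them the phantom is nearly
mirror-symmetric, and because the augmentation protocol includes
horizontal flips, anterior/posterior landmark identity becomes
ill-posed — a property of an inadequate phantom, not of the method, and
one that real knee anatomy does not share.

What passing on phantoms does **not** show: robustness to the texture,
exposure variation, soft tissue and true 3D projection effects of
clinical radiographs. The phantom validates the machinery (encodings,
optimization, decoding, planning geometry), not clinical performance.

The `intraoperative` preset raises implant overlap (0.8), shaft
truncation (0.7), bilateral exposure (0.3) and noise, mirroring mobile
C-arm acquisitions; the `diagnostic` preset keeps them low (0.25 / 0.2 /
0.02).

## Evaluation metrics

Segmentation is scored by the Dice coefficient averaged over foreground
and background (a channel empty in both scores 1) and by the average
symmetric surface distance with contours densely resampled to 0.5 px
spacing — ASSD measures curves, not vertex placement, so polygon vertices
alone would bias it. Keypoints use the Euclidean distance (px, and mm
when calibrated). Lines are compared through raw image moments after
truncation at the 2-sigma likelihood: centroid `(M10/M00, M01/M00)` and
orientation `gamma = 0.5 atan2(2 mu'11, mu'20 - mu'02)` in `(-90, 90]`.
The factor 2 on the mixed moment is the standard second-moment
orientation formula; the rotation-recovery property test (generating
angle recovered within 0.5 degrees across a sweep) validates this
reading. Test-set aggregation reports the median with a seeded percentile
bootstrap 95% CI (10,000 resamples by default); cancelled plans are
excluded from distance statistics and counted separately.

## Scaled-down study conditions

The package's self-contained experiment trains the multi-head model on
200 phantoms at 64 x 64 (140/30/30 split), 24 constant channels, depth 4,
heatmap `sigma` 4.5 px (the encoding scale reduced with the raster), 20
epochs, once with uniform and once with GradNorm weighting, from the same
initialization and data seed; held-out keypoints are decoded with the
sub-pixel Gaussian fit. These sizes are a desk-scale configuration of the
protocol and are what the acceptance suite runs. Reported quantities:
validation composite loss at the selected epoch versus epoch 1, held-out
fg/bg Dice, median keypoint error, and the uniform-vs-GradNorm comparison
of the latter.

At 1/20th or so of the reference protocol's update count, the
heatmap-regression task is the one that underfits first: thin-structure
landmarks on the tibial plateau remain substantially less precise than
the femoral ones, while segmentation converges quickly and GradNorm
consistently shifts capacity toward the keypoint and line tasks (the
weighting comparison above). Absolute keypoint precision at this budget
should be read with that in mind; the acceptance suite reports it
unvarnished.

## Known limitations

* The hourglass layer plan (channel count, depth, head shape) follows the
  architectural description, not a verified layer listing; all are
  configuration.
* Registration of a finished plan onto subsequent live images is out of
  scope, as is 3D trajectory planning.
* The training engine is single-threaded CPU R/C++; it is sized for the
  phantom experiments, not for clinical-resolution training runs.
* Blueprint constants ship as literature-informed defaults only; the
  package makes no clinical claim for them.
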