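---
title: "Methods: adaptive vitiligo patch detection and population occurrence mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adaptive vitiligo patch detection and population occurrence mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitimap)
```

## The problem and the acquisition assumption

Vitiligo vulgaris depigments patches of skin; on fair phototypes the patches
are nearly invisible under white light. Under black-light (Wood's lamp,
about 365 nm) illumination the depigmented epidermis fluoresces, which is
the standard dermatological examination condition. `vitimap` assumes its
input photographs were acquired that way: the patch signal then sits mainly
in the blue channel, secondarily in green, while red carries the overall
skin tone. Nothing in the package attempts color calibration; all intensity
reasoning is relative within a photograph, which is exactly why the
detection threshold is adaptive (below).

## Working resolution and intensity domain

Every photograph is rescaled on ingest to 610 × 407 pixels (bilinear
interpolation, aspect mismatch ignored), the size of the face template.
A fixed grid makes pixel counts comparable across cameras and years of
acquisition, and patch areas are pixel counts. Intensities are mapped from
the native bit depth to floats in [0, 1] (8-/16-bit codes divided by the
maximum code value), so all threshold arithmetic is bit-depth independent.
Masks are written as 8-bit 0/255 grayscale PNG and round-trip exactly.

The interpolation kernel and the aspect policy are our choices — bilinear
and plain stretching — made for determinism; the registration step absorbs
moderate geometric distortion anyway because it rescales per face ellipse.

## Contrast filters

Four single-channel filters map the RGB image to the gray image that is
thresholded; all outputs are clipped to [0, 1]:

* **Filter 1**: `B`.
* **Filter 2**: `1 − luma(R/B, G/B, B/B)` with BT.601 weights
  (0.2989, 0.5870, 0.1140). The ratio image is dark where blue dominates, so
  the complement makes patches bright. Where `B < 1/255` the divisor is
  floored at `1/255`: elementwise division is otherwise undefined on the
  black background, and an epsilon floor keeps the output finite without
  affecting any pixel that carries real signal. Note the weights sum to
  0.9999, so an achromatic pixel maps to exactly `1e-4`, not 0.
* **Filter 3**: `clip(B − R, 0, 1)`.
* **Filter 4** (default): `clip(G + B − R, 0, 1)` — the two fluorescence
  channels summed, normalized against skin tone via the red subtraction.

Negative differences are clipped rather than rescaled: rescaling would
destroy the absolute-intensity semantics that the adaptive threshold needs
(a ROI's maximum must mean "brightest patch pixel", not "brightest after an
image-wide affine remap"). The complement in filter 2 is taken in float,
before any quantization.

## ROIs and the adaptive threshold

The user (or the synthetic generator) supplies polygonal regions of
interest — rough contours around candidate patches, ideally one per region
of roughly even illumination. Rasterization uses the even-odd rule with the
boundary counted inside, consistent with the "greater or equal" convention
of the threshold itself; pixel (row r, col c) has centre (x, y) =
(c − 1, r − 1), 0-based.

Within ROI *i* with maximum filtered intensity `max_i`, a pixel is detected
iff `f ≥ T · max_i`, where `T ∈ [0, 1]` is the single global threshold
(default 0.5). Consequences that the tests assert directly:

* `T = 0` detects the whole ROI — this is also the manual-contouring
  fallback (`manual_patch()`) for patches the automatic rule cannot catch;
* `T = 1` detects only the pixels attaining the ROI maximum;
* masks shrink monotonically as `T` grows;
* multiplying the filtered image by any positive gain leaves the mask
  unchanged (the cutoff scales with the maximum);
* pixels outside every ROI can never influence the result.

Overlapping ROIs combine by union, matching an independent per-ROI loop
accumulating into one image. A ROI whose maximum is exactly 0 is degenerate
(no signal at all); detecting its entire area would follow formally from
`f ≥ 0`, but that turns flat-dark regions into spurious full-ROI patches, so
the package instead warns and detects such a ROI only at `T = 0`.

## Registration and the occurrence map

The face contour is an axis-aligned ellipse (centre, semi-axes `a`, `b`);
face area is `πab`. Registration onto the 610 × 407 template maps each
detected pixel by

```
x' = round(cx_t + (x − cx_p) · a_t / a_p)
y' = round(cy_t + (y − cy_p) · b_t / b_p)
```

with `round` being round-half-away-from-zero (stated explicitly because
languages disagree on half-way cases). The horizontal semi-axis drives the
x scaling and the vertical one the y scaling — the only geometrically
sensible pairing. Points mapping outside the frame are dropped with a
warning, not clamped: clamping would pile mass onto the frame border of the
occurrence map. The registered mask is re-binarized, so a patient whose
pixels merge under a contractive mapping still contributes at most 1 to any
cell.

The occurrence matrix starts at zero and accumulates the registered binary
masks; dividing by the cohort size N gives percentages, so every cell is
`100·k/N` for some integer count k. Upscaling (patient ellipse smaller than
the template) can leave rounding gaps — visible as zero-occurrence streaks
in small cohorts; the package keeps the plain rounding scheme rather than
interpolating, and the effect washes out as N grows. Cohort filters (gender,
familiarity, onset age, first-visit year, onset-to-visit delay in whole
years) subset the records before accumulation; a criterion on a field absent
from every record (e.g. onset age without a `birth_date` column) is skipped
with a warning rather than silently emptying the cohort.

The bundled template is a synthetically drawn neutral face with ellipse
`{cx = 305, cy = 203.5, a = 230, b = 150}` on the landscape 610 × 407
frame — arbitrary but fixed, replaceable via a template JSON config; no
clinical template image is distributed with the package.

## Validation metrics

Against a gold-standard mask, the success rate is
`100 · tp / (tp + fp + fn)`: true-positive area over the union of marked
and detected areas. The union denominator is the only choice for which
100% means perfect agreement and 0% means disjoint masks, and it makes the
score invariant to jointly-background pixels. Two empty masks score 100
with a warning (no lesion, no disagreement). Overlays use green/red/blue
for agreement/false positive/false negative.

The threshold sweep reruns detection at `n` evenly spaced thresholds
(default 7 over [0.35, 0.65], i.e. ±30% around the 0.5 default) and maps
the percentage of runs detecting each pixel. By monotonicity the detecting
runs form a prefix of the ascending threshold list, so cells take values
`100·k/n`, and the 100-valued core equals the detection mask at the top
threshold exactly.

## The synthetic generator

`generate_scene()` renders, deterministically per seed: a dark background
(0.05), an elliptical face filled with red-dominant skin
(R, G, B) = (0.55, 0.30, 0.25), elliptical patches that add
`green_boost = 0.15` to G and `blue_boost = 0.3` to B, a linear
multiplicative illumination ramp (default strength 0.2, random direction),
optional overexposed ellipses (pushed to 0.98), optional beard speckle
(multiplicative, amplitude 0.15) and dark occlusion bars (0.03), then
additive Gaussian noise (σ = 0.01 per channel). The ground truth is the
exact union of the rasterized patch blobs inside the face, minus occluded
pixels — a black hair strand is genuinely not detectable as vitiligo, so it
does not belong to the truth either. The emitted session holds one ROI per
patch (the patch ellipse radially dilated by 5 px, mimicking rough manual
contouring), filter 4 and threshold 0.5.

These values are the generator's fixed study conditions: the boosts sit an
order of magnitude above the noise, as black-light patch contrast does in
practice, and the skin color makes the filter-4 skin response clip to ~0.
`generate_cohort()` samples per-patient face ellipses at least as large as
the template's, so registration is contractive and designed occurrence
regions (`occurrence_design`) map onto their template footprint without
rounding gaps — which is what lets aggregation tests predict occurrence
percentages exactly.

What the generator does **not** emulate: real facial anatomy and curvature
shading, specular highlights on sebum, residual make-up fluorescence,
camera spectral response to UV, soft (gradual) patch borders, and
freehand-quality gold standards. Passing tests therefore demonstrate the
pipeline's arithmetic, geometry and robustness properties — not clinical
accuracy on photographs, where patch borders are the dominant source of
disagreement with expert markings and per-patient parameter tuning is
expected.

## Numerical choices and degenerate inputs

* Boundary pixels: inclusive (≥) everywhere — polygon boundary, ellipse
  boundary, threshold comparison.
* Filter 2 divisor floor: `1/255` (one 8-bit intensity level).
* Rounding: half away from zero, used only in registration.
* Degenerate ROIs (outside the frame, zero rasterized area, all-dark) and
  invalid parameters (empty ROI lists, thresholds outside [0, 1], non-3-channel
  images, duplicate patient ids, onset after first visit) raise immediate
  validation errors or warnings as described above.

## Problem sizes in the test suite

The suite exercises full-resolution (610 × 407) images for the pipeline and
cohort paths (cohorts of 3–10 synthetic patients) and small grids (≤ 40 ×
40, with ≤ 32 × 32 for brute-force oracle comparisons) for the exhaustive
pixelwise checks, keeping the default run to well under a minute of compute
for the geometry suites and a few seconds per synthetic cohort.

## Known limitations

Axis-aligned ellipses cannot represent head tilt; the registration is
similarity-like (two axis scalings plus translation), not landmark-based.
Occurrence-map cells are not statistically tested for regional differences,
and no semantic face parcellation (eyelid, mouth, ...) is provided. The CLI
holds no interactive drawing: ROIs come from session JSON files, produced
elsewhere or by the generator.
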