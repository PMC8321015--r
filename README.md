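# vitimap

Semi-automatic detection and population mapping of facial vitiligo patches
in black-light photographs.

Vitiligo vulgaris produces depigmented skin patches that can be nearly
invisible on fair phototypes under white light. Under ~365 nm black-light
(Wood's lamp) illumination the depigmented epidermis fluoresces, and the
patch signal concentrates in the blue (and, weaker, green) channel of an RGB
photograph. `vitimap` implements a pipeline for dermatology research built
on that observation:

1. **Ingest** — every photograph is rescaled to a fixed 610 × 407 working
   resolution, so pixel-count area measures are camera independent.
2. **Channel-arithmetic filters** — four single-channel contrast images:
   `B` (filter 1), the complement of the gray-converted `(R/B, G/B, B/B)`
   ratio image (filter 2), `clip(B − R)` (filter 3) and `clip(G + B − R)`
   (filter 4, the default: the two fluorescence channels summed, normalized
   against the skin tone carried by red).
3. **Per-ROI adaptive thresholding** — the user supplies rough polygonal
   regions of interest; inside ROI *i* a pixel is detected when
   `f(x, y) ≥ T · max_i`, where `T ∈ [0, 1]` is the single user-set global
   threshold (default 0.5) and `max_i` the maximum filtered intensity in
   that ROI. Detection therefore adapts to each region's own brightness:
   shady and overexposed areas segment correctly when given their own ROIs.
   `T = 0` takes the whole ROI (manual contouring); `T = 1` keeps only the
   ROI maxima.
4. **Registration and occurrence mapping** — each patient's binary mask is
   scaled axis-wise by the ratio of a template face ellipse to the patient's
   face ellipse, translated centre-to-centre, rounded, and re-binarized;
   summing the registered masks over a cohort and normalizing by the cohort
   size gives a per-pixel occurrence percentage displayed over the face
   template, with cohort filters (gender, familiarity, onset age, first
   visit year, onset-to-visit delay).
5. **Validation** — detected masks are scored against gold-standard masks by
   the success rate `100 · tp / (tp + fp + fn)` (true-positive area over
   union area), and a global-threshold sweep over [0.35, 0.65] maps how
   stable each detected pixel is around the default threshold.
6. **Synthetic faces** — a seedable generator produces black-light-like face
   images with exact ground truth (elliptical face, red-dominant skin,
   blue/green-boosted patches, illumination gradients, overexposure, beard
   texture, occlusion bars), so the whole pipeline is testable without
   patient data.

## Worked example

```r
library(vitimap)

dir <- file.path(tempdir(), "demo")
generate_cohort(5, 42, dir)                     # 5 synthetic patients

img  <- load_image(file.path(dir, "P01.png"))   # 407 x 610 x 3 in [0,1]
ses  <- read_session(file.path(dir, "P01.json"))
ses
#> Annotation session: 6 ROI(s), filter 4 , global threshold 0.5

mask <- detect_patches(apply_filter(img, ses$filter_id), ses$rois,
                       ses$global_threshold)
round(attr(mask, "adaptive_thresholds"), 4)
#> 0.2196 0.2333 0.2353 0.2373 0.2216 0.2235
sum(mask)                                        # detected pixels
#> 4557
patch_area_fraction(mask, ses$ellipse)           # ~2.7% of the face area
#> 0.0271

gt <- load_mask(file.path(dir, "P01_truth.png"))
compare_masks(mask, gt)
#> tp: 4557  fp: 0  fn: 0  success rate: 100.00%

tpl <- default_template()
masks <- lapply(sprintf("P%02d", 1:5), function(id) {
  s <- read_session(file.path(dir, paste0(id, ".json")))
  m <- detect_patches(
    apply_filter(load_image(file.path(dir, paste0(id, ".png"))), 4),
    s$rois, 0.5)
  register_mask(m, s$ellipse, tpl$ellipse)
})
om <- accumulate_masks(masks)
om
#> Occurrence map over 5 patient(s) [ all patients ]
#>   nonzero cells: 13554, max occurrence: 60.0%
save_image(render_map(om, tpl), "map.png")

threshold_sweep(apply_filter(img, 4), ses$rois)  # default 0.35-0.65, 7 steps
#> Stability map over 7 thresholds in [0.35, 0.65]: 4557 pixel(s) stable at 100%
```

Each of the six per-ROI adaptive thresholds is `0.5 ×` that ROI's maximum
filter-4 intensity; on this synthetic patient every ground-truth pixel is
recovered with no false positives. Across the 5-patient cohort the
occurrence map peaks at 60% — three of the five patients overlap at those
template coordinates — and the stability map shows the entire detected area
surviving the whole swept threshold range.

A command-line wrapper covering the same pipeline
(`simulate`, `ingest`, `detect`, `aggregate`, `validate`, `sweep`) ships at
`system.file("cli", "vitimap", package = "vitimap")`:

```sh
vitimap simulate --n 5 --seed 42 --out fixtures/
vitimap detect --image fixtures/P01.png --session fixtures/P01.json \
        --out P01_mask.png
vitimap validate --detected P01_mask.png --gold fixtures/P01_truth.png
```

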