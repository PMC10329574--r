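# polypval

Validation metrics for polyp detection are not a fixed yardstick: the
numbers a study reports depend on the test set composition (which clinical
center, which polyp sizes) and on metric hyperparameters that are often
adopted unexamined — the localization criterion, its IoU threshold, and the
confidence cutoff. `polypval` is an R toolkit for making those dependencies
visible. It evaluates object-level polyp detections on multi-center
single-frame datasets under configurable localization criteria, and ships a
seeded synthetic-data generator so that every analysis stage can be
exercised, tested and demonstrated without access to clinical data.

It is written for researchers validating colonoscopy detection algorithms
and for methodologists studying metric behavior.

## What it computes

A **localization criterion** decides whether a predicted box `P` hits a
reference polyp `R`:

* overlap-based: Box IoU, Mask IoU, Hull IoU — `IoU(P, ref(R)) ≥ τ` where
  `ref(R)` is the bounding box, the segmentation mask, or its convex hull
  (`Mask IoU > 0` is the permissive position criterion expressed at `τ = 0`,
  with a strict inequality);
* point-based: the center point of `P` inside box / mask / hull of `R`;
* center distance: `‖c(P) − c(R)‖ ≤ τ` pixels.

Ambiguous matchings are resolved by the COCO-style greedy one-to-one
assignment (descending confidence, best score, deterministic tie-breaks).
On the resulting object-level confusion counts the package computes

* Sensitivity `TP/(TP+FN)`, PPV `TP/(TP+FP)`,
  `F_β = (1+β²)·PPV·Sens/(β²·PPV+Sens)`;
* 101-point interpolated Average Precision
  `AP = (1/101) Σ_{r∈{0,.01,…,1}} max{prec at recall ≥ r}` over the pooled
  confidence sweep, per-threshold sweeps `AP(τ)`, and range means such as
  `AP@0.5:0.95`;
* per-center metric panels, size-stratified AP (small < 100², large > 200²
  pixels at 1920×1080, scaled to the image resolution) with across-center
  sample SD, criterion-comparison tables, and agreement fractions against
  binary clinician usefulness ratings.

## Worked example

```r
library(polypval)

spec <- default_six_center_spec(seed = 7, scale = 0.05, resolution = c(640, 360))
ds <- generate_study(spec)
ds
#> <pv_dataset: 75 images, 68 references, 71 predictions, 71 ratings, 6 centers>

metric_panel(ds, criterion("box_iou", 0.5), confidence_cutoff = 0.5)
#> # A tibble: 7 × 4
#>   metric      value criterion      confidence_cutoff
#>   <chr>       <dbl> <chr>                      <dbl>
#> 1 sensitivity 0.353 box_iou >= 0.5               0.5
#> 2 ppv         0.923 box_iou >= 0.5               0.5
#> 3 f1          0.511 box_iou >= 0.5               0.5
#> 4 f2          0.403 box_iou >= 0.5               0.5
#> 5 ap@0.5      0.432 box_iou >= 0.5               0.5
#> 6 ap@0.75     0.115 box_iou >= 0.5               0.5
#> 7 ap@0.5:0.95 0.161 box_iou >= 0.5               0.5
```

The panel reads: at a Box-IoU-0.5 criterion with confidence cutoff 0.5 the
simulated detector finds 35% of the polyps, 92% of its kept boxes are
correct, and the COCO-style `AP@0.5:0.95` (0.161) is far below `AP@0.5`
(0.432) — the threshold range, not the detector, drives much of the
difference. (This small desk-scale study uses 640×360 frames, where the
generator's absolute 15-pixel localization jitter is relatively harsh;
full-resolution studies score higher.) Downstream reports follow the same
grammar:

```r
size_stratified_ap(ds, "box_iou")          # per center x size class, AP@0.5 / AP@0.5:0.95
criterion_comparison(ds)                   # Sens/PPV/F1/F2/AP across criteria
agreement_fractions(ds)                    # agreement with (simulated) clinician ratings
autoplot(pr_curve(ds, criterion("box_iou", 0.5)))
```

A command-line wrapper with `generate`, `evaluate`, `sweep`, `stratify`,
`compare` and `agree` subcommands is installed at
`inst/cli/polypval.R` (see `?cli_main`).

## Vignette

`vignettes/validation-metrics.Rmd` documents the model and its conventions:
criterion semantics and tie-breaks, AP interpolation, stratification
("ignore") rules, the synthetic generator's assumptions and its
negative-control design, and known limitations.
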