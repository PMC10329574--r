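---
title: "Validation metrics for polyp detection: model, conventions, and synthetic studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validation metrics for polyp detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`polypval` evaluates object-level polyp detections under configurable
localization criteria and quantifies how sensitive the resulting
performance numbers are to validation design choices: the clinical center
the test data came from, the polyp size distribution, the criterion family
and its threshold, and the confidence cutoff. This vignette is the
package's own account of the underlying model: what exactly is computed,
which conventions were open and how they were fixed, what the synthetic
generator does and does not emulate, and what the tests consequently do and
do not establish about real data.

## The data model

A dataset couples four tables: frames (`image_id`, pixel dimensions,
`center_id`, `patient_id`), reference polyps (binary segmentation mask,
morphological type flat/protruded, pixel area), detector predictions
(axis-aligned box with a confidence in [0, 1]) and optional binary
clinician usefulness ratings attached to predictions. The
center/patient/image nesting is carried through every report so that
hierarchical analyses (e.g. a mixed-effects model of per-object IoU on
size and type with center/patient/image as grouping factors, via
`object_iou_table()` and any modelling package) remain possible; the model
fit itself is deliberately out of scope.

Geometry lives on an integer pixel grid. Pixel `(r, c)` occupies the unit
square `[c, c+1) × [r, r+1)`; boxes are half-open `[x0, x1) × [y0, y1)`.
These conventions make areas and IoU exact integer arithmetic for integer
boxes and remove all boundary ambiguity. Two conventions deserve
highlighting:

* **Convex hulls** are hulls of the union of foreground unit squares,
  rasterized by pixel-center inclusion (boundary counts as inside). Hulls
  of pixel *centers* would violate `mask ⊆ hull` for degenerate
  (single-pixel, collinear) masks; the unit-square hull guarantees the
  containment chain `mask ⊆ hull ⊆ bounding box` on which the criterion
  orderings rest.
* **Point membership** assigns a continuous point to the pixel containing
  it by flooring both coordinates; a point on an exact pixel boundary
  belongs to the pixel at its lower right. This is an arbitrary but
  deterministic tie-break.

Non-integer prediction boxes (legal in the COCO results dialect) are
rasterized by the same pixel-center rule before any mask or hull IoU is
computed, so all overlap scores are ratios of pixel counts; box–box IoU
uses the closed rectangle form, which equals the raster computation for
integer boxes (a tested invariant).

## Localization criteria

A criterion is a `(kind, threshold)` pair:

* overlap kinds `box_iou`, `mask_iou`, `hull_iou` compare the predicted box
  against the reference's bounding box, mask, or hull. The hit rule is
  `score ≥ τ` for `τ > 0` and `score > 0` for `τ = 0`, so the permissive
  "any overlap with the mask" criterion (`mask_iou > 0`) is expressible as
  threshold zero without a separate code path.
* point kinds `point_in_box`, `point_in_mask`, `point_in_hull` test the
  predicted box center; the threshold is ignored.
* `center_distance` accepts when the Euclidean distance between the
  predicted box center and the reference center is at most `τ` pixels. The
  reference "center" is ambiguous in common usage — both the mask centroid
  and the bounding-box center are defensible — so both are implemented;
  the default is the mask centroid because it tracks the polyp's position
  rather than the annotation box's slack. `τ = "equiv_radius"` uses the
  per-reference equivalent radius `sqrt(area/π)`, which scales the
  tolerance with the object.

For non-convex (flat) polyps the point-based criteria genuinely disagree:
a box center in a concavity is outside the mask but inside the hull. The
synthetic generator's crescent shapes exercise this case on purpose.

## Assignment and counting

Ambiguities (two predictions hitting one reference) are resolved by greedy
one-to-one assignment in descending confidence, ties by `pred_id`; each
prediction takes the unmatched reference with the best score, ties by
smaller center distance, then `ref_id`. Greedy-by-confidence is the
standard convention of AP tooling and makes the prefix property hold
exactly: the matching after the top-k predictions of the confidence sweep
equals matching those k predictions alone, which is what lets one
incremental sweep produce the whole precision–recall curve. In polyp
frames multiple objects are rare, so the choice of assignment strategy
matters far less than the criterion; optimal (Hungarian) assignment is a
possible extension, not implemented.

Counting metrics are computed at an explicit confidence cutoff that is
echoed into every report — the package treats it as a first-class
hyperparameter, defaulting to 0.5 as a reporting convention, precisely
because counting metrics are silently sensitive to it. Undefined values
(PPV with no kept predictions, sensitivity with no references in scope)
are reported as absent (`NA`), never coerced to 0; `F_β` is 0 when both
precision and recall are 0.

## Average precision

The precision–recall sweep pools predictions across all images of the
evaluation scope (micro pooling; per-center numbers restrict the scope
first), ranks them by descending confidence with `pred_id` as the
deterministic tie-break, and emits cumulative (recall, precision) points.
AP is the 101-point interpolation: the mean over recalls `{0, 0.01, …, 1}`
of the maximum precision at or beyond that recall, zero when no point
reaches it. An all-point area-under-curve variant exists behind a flag for
sensitivity analysis; it is never the default. Because ties are broken
deterministically, AP is reproducible bit for bit, and it is invariant
under any monotone transformation of the confidences (a tested property).

`ap_threshold_sweep()` computes pair scores once and re-applies only the
hit rule along the threshold grid, so Fig-style threshold curves cost one
scoring pass. AP is expected to be non-increasing in the threshold; with
greedy matching this is not a theorem, so the suite asserts it empirically
over seeded studies and any violation would surface as a test failure
rather than being silently accepted.

## Stratified reporting

Polyp size classes are defined at a 1920×1080 reference resolution — small
below `100²` pixels, large above `200²`, medium otherwise, boundaries
inclusive to medium — and both thresholds scale with
`(width·height)/(1920·1080)` for other resolutions, so "small" means the
same fraction of the frame everywhere.

Size-stratified AP uses ignore semantics: for the small-class sweep,
predictions matched to medium or large references are removed from the
ranking rather than counted as false positives; unmatched predictions
remain false positives for every class. Without this, a detector would be
punished in the small-class cell for correctly finding a large polyp.
"All centers" cells are pooled (micro) computations, not means of
per-center values — the two genuinely differ — and the across-center
spread is the sample standard deviation (denominator n−1) of the
per-center values, which is zero iff all centers agree.

One consequence of ignore semantics worth knowing: the false positives are
*shared* across the per-class sweeps while the true positives are not, so
a class with fewer references suffers proportionally more precision
contamination. This is a property of class-stratified AP itself, not of
any detector, and it shapes the negative-control design below.

## Agreement with clinician ratings

A rated prediction meets a criterion when its pair with *any* reference on
its image is a hit; no assignment is involved, and a prediction on a frame
without polyps can never be accepted. Per criterion the report gives the
fraction of "useful"-rated predictions accepted and of "not useful"-rated
predictions rejected; an empty rating class yields an absent fraction, and
both fractions are backed by integer counts. The default criterion
families compared are position-focused (point in box/mask/hull, center
distance at the equivalent radius) and outline-focused (box/mask/hull IoU
at 0.5, plus `mask_iou > 0`); the exact list is a package default and
fully overridable, since no single canonical list exists.

## The synthetic generator

The generator emulates the *statistical structure* the analyses depend on,
not endoscopic appearance: multi-center single-frame datasets with
per-center frame counts and polyp prevalences, a polyp size mixture with
truncated log-normal areas per class, convex ellipses standing in for
protruded polyps and non-convex crescents (an ellipse with an elliptical
bite) for flat ones, and a patient hierarchy assigned round-robin. The
shipped six-center default (256/276/457/227/208/88 frames at prevalences
98/89/99/64/99/94%, 1920×1080) matches the scale of a realistic
multi-center test set; 5% of polyp-bearing frames carry a second polyp.
Default mixtures (size 0.25/0.45/0.30, shape 0.7/0.3 ellipse/crescent) are
plausible stand-ins chosen once — the true distributions of any particular
clinical dataset are not public — and everything generated is labelled
synthetic.

The detector stand-in perturbs each reference box with:

* a miss draw, logistic in log-area (midpoint 6000 px at 1920×1080, slope
  1.28), so small polyps are missed more — roughly 34% at the small/medium
  boundary and 3% for large polyps;
* Gaussian center jitter, absolute in pixels by default (sd 15 px);
* a common log-normal scale factor on width and height (sd 0.1 on the log
  scale), clipping to the canvas;
* confidence = realized mask IoU + Gaussian noise (sd 0.1), clipped to
  [0, 1], so confidence ranks track quality as real detectors' do;
* Poisson false positives (rate 0.2 per frame) with Beta(2, 5)
  confidences.

Absolute-pixel jitter is the hypothesized mechanism behind the polyp-size
effect: a 15-pixel displacement is fatal for a 70-pixel box and irrelevant
for a 400-pixel one, so stratified AP rises steeply with size class. The
ratings simulator labels each prediction useful iff it hits under a
generating criterion (default `mask_iou > 0`), then flips labels with a
configurable noise probability.

**Negative control.** `negative_control_spec()` removes every size-linked
mechanism: jitter becomes relative to the box extent (sd 0.15 of
width/height per axis), the miss rate becomes size-independent, and the
size mixture is made uniform. The last step is needed because of the
shared-false-positive property above: even with perfectly size-invariant
localization behavior (verified: per-object hit rates and confidences are
flat across classes under relative jitter), unequal class counts alone
reorder the per-class APs. With composition equalized, the size-class AP
gaps collapse to noise, while the default absolute-jitter study keeps
gaps well above 0.05 — together these two arms demonstrate that the size
effect in the synthetic study is produced by the localization mechanism,
not by bookkeeping.

What the generator does **not** emulate: image content (no pixels are
synthesized beyond masks), video sequences and tracking, annotation
disagreement between raters, detector failure modes that are not
box-geometric (duplicate boxes, drift with image artifacts), and any
correlation between polyp morphology and detector quality beyond the
convex/non-convex distinction. Tests passing on synthetic data therefore
establish the *metric machinery* — not that any particular detector
performs at any level on clinical data.

## Determinism and numerical choices

All generation flows through R's RNG from a single integer seed
(`generate_study()` derives reference/prediction/rating streams as seed,
seed+1, seed+2); fixed seed means byte-identical datasets and reports, and
the serializers write canonical key-sorted JSON at full floating-point
precision so that read–write round-trips are exact. Scanline
rasterization of hulls and polygons uses a 1e-7 tolerance on the
pixel-center inclusion test; because every mask pixel center sits at least
0.5 pixels inside the hull, the tolerance cannot break the containment
chain. Degenerate inputs fail loudly with classed errors (empty masks,
dangling identifiers, out-of-range confidences, shapes that cannot fit the
canvas) rather than being repaired silently.

## Problem sizes used by the test suite

The suite runs the full-scale six-center study (1512 frames, ~1450
objects) for the size-effect and control experiments (10 seeds per arm)
and smaller seeded studies (roughly 60–90 frames at 640×360) for
property-style checks — threshold monotonicity, criterion containment,
round-trips — where the property, not the scale, is under test. Oracle
comparisons use ≤ 5-image instances where brute-force matrix geometry,
naive greedy matching and an explicit precision-envelope AP are feasible
and exact. These sizes are the package's own choices balancing coverage
against iteration speed.

## Known limitations

* Greedy assignment only; no Hungarian or double-counting variants.
* No video/sequence evaluation, no rotated boxes, no 3D, no DICOM.
* Stratified AP inherits the shared-false-positive composition property
  discussed above; comparing per-class APs across datasets with different
  class mixtures conflates mechanism and composition — which is, in part,
  the point the toolkit exists to make visible.
* The mixed-effects analysis of per-object IoU is exported as a table, not
  fitted internally.
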