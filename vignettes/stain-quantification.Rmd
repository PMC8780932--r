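---
title: "Trainable color-palette quantification of stained histology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trainable color-palette quantification of stained histology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stainpal)
```

## The problem

Brightfield histology quantification often reduces to one question: what
fraction of a field of view is covered by a stain of interest? Fat
vacuoles on H&E, collagen on Sirius red, fibrin in occluded vessels on
MSB, or brown DAB-labeled nuclei against blue hematoxylin counterstain
are all, at the pixel level, color-classification problems. Hand tracing
is accurate but slow and subjective; fixed per-channel thresholds
("color thresholding") are fast but force the positive class into an
axis-aligned box in RGB space, which real stains — blends of red, green
and blue — do not respect.

`stainpal` implements the trainable alternative: learn a *palette* of
positive colors from a handful of user-annotated polygon regions on two
to four representative training images, then classify entire image
batches pixel by pixel against that palette.

## The model

**Color map.** RGB space is discretized into `levels` uniform bins per
channel (`floor(channel * levels / 256)`, default `levels = 64`, i.e.
4-value-wide bins). For every pixel inside an annotated polygon, the
occurrence count of its quantized color under the region's label (a
positive class or `"negative"`) is incremented. The resulting sparse
table of per-color, per-class counts is the *color map*. Counts, not
labels, are the model: a pixel covered by two conflicting regions
increments both counts and simply dilutes that color's evidence.

**Positive color list.** A quantized color joins class *c*'s palette
when its share of that color's total training occurrences strictly
exceeds `threshold` (default 0.5, a strict majority). With several
positive classes the share is computed for the class with the largest
count against *all* other counts combined, so a color belongs to at most
one class and the per-class palettes are disjoint by construction.
Classification is then a pure per-pixel lookup — deterministic, order
independent, and linear in image size.

**Unseen colors.** Colors never observed in training default to
negative, a deliberately conservative choice that avoids false positives
on novel hues; `unseen_policy = "nearest"` instead adopts the label of
the nearest observed quantized color (Euclidean distance in bin-index
space, ties resolving to negative).

**Re-training.** Color maps merge by entrywise count addition
(commutative, associative, and scale invariant at palette level), so a
second annotation pass over problem images updates the model without
discarding the first pass — `merge_training()` / `--merge-with`.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `levels` | 64 | bins/channel | 4-wide bins absorb sensor noise yet separate visually distinct shades; exposed because very noisy material may want 32 |
| `threshold` | 0.5 | fraction | strict majority is the weakest rule that makes "positive color" unambiguous |
| `unseen_policy` | `negative` | — | conservative default; `nearest` generalizes across small staining shifts |
| `background_min_channel` | 220 | channel value | blank slide is near-white under brightfield; a pixel is background iff all three channels reach this |
| `min_component_area` | 0 | px | raise to drop debris/speckle below the feature scale |
| `connectivity` | 8 | — | matches the visual continuity of stained features; 4 available |
| `morphology` | none | — | `open`/`close`/`fill_holes` with a disc element, radius in px |

The post-processing order is fixed by default and recorded with every
run: background exclusion, then morphology, then size filtering — size
thresholds should act on final, cleaned components. Whether the original
interactive tool applied morphology before or after size filtering is
not documented anywhere we could check; the order here is a deliberate,
stated choice. Morphology uses `EBImage::makeBrush(2r + 1, "disc")`;
out-of-image neighborhoods count as foreground during erosion (and
background during dilation), so features touching the field border are
not artificially eroded.

## Geometry conventions

All counts depend on one rasterization convention, so it is fixed:
pixel (row *i*, column *j*), 0-based, has center `(j + 0.5, i + 0.5)`;
a pixel belongs to a polygon when its center is inside under the
even-odd rule, evaluated as a leftward ray-crossing test with strict
inequalities. For integer-coordinate polygons this behaves half-open
(left/top edges in, right/bottom out), so abutting annotations never
double-count a pixel. The test suite checks the implementation against
exhaustive pixel-center point-in-polygon testing with an independent
implementation (`mgcv::in.out`) on random polygons.

## Quantification and evaluation

Per image and class the package reports percent positive area
(`100 * positive / denominator`), component counts and component-area
order statistics. The denominator is the whole field by default —
matching how percent area is conventionally reported — with
`tissue_only` (excluding near-white background) available; the mode used
is recorded in every report row. Batch summaries use midpoint-interpolated
medians (`stats::median`) and interquartile ranges. Two-class area
ratios (e.g. brown DAB-positive to blue counterstained nuclear area)
propagate an empty denominator as a missing value, never as zero, and
batch summaries count those misses.

Against reference tracings the package computes the pixel confusion
matrix (optionally restricted to an evaluation region) and, from those
four integer counts alone: sensitivity, specificity, precision,
accuracy, Youden's J (`sensitivity + specificity - 1`), F-score
(`2TP / (2TP + FP + FN)`), and the Matthews correlation coefficient
(`(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, in double
precision so image-scale counts cannot overflow). When several
annotators supply tracings, the consensus standard is their
intersection — a pixel is true only if everyone marked it; majority
vote is offered as an explicitly non-default option. When a prediction
is constant the MCC denominator vanishes; the package returns 0 with a
degeneracy flag — the chance-level convention — so batch tables stay
rectangular. Per-image metrics and micro-averaged pooled metrics
(metrics of the summed counts, *not* means of per-image metrics) are
both reported.

## The synthetic generator, and what it does not show

`generate_synthetic()` paints a noisy tissue-colored background,
elliptical or star-convex features with per-pixel color noise, and an
optional near-white slide margin, recording pixel-exact truth masks at
paint time. Noise is independent per pixel and channel, uniform on
`±spread` and clamped to `[0, 255]` — chosen for exact reproducibility
and easy separability reasoning, not as a camera model. Identical spec
and seed give byte-identical images; feature placement is rejected
rather than allowed to overwrite another class's pixels; requested area
fractions are checked for feasibility (at most 80% of the paintable
interior) before any drawing.

`generate_training_pair()` mirrors the interactive training workflow:
it emits two images from the same spec plus polygon annotations —
12-gons inscribed well inside sampled features (shrunk further until
every covered pixel is pure class truth) and square background patches
verified to contain no feature pixels. It samples the 12 largest
features per class per image by default: representative training is the
method's own prerequisite, and sampling too few, too-small polygons
under-samples a class's color distribution, which shows up directly as
undercalling of that class.

The `"blend"` preset exists to exercise the one structural weakness of
box thresholding: its positive colors lie on an anti-diagonal band
(`r + g ≈ 280` within ±16) while the background fills the rest of the
(r, g) square at a guard distance of ≥ 40 from the band. Every
single-channel marginal of the positive colors overlaps the background,
yet the joint distributions are disjoint — after 4-wide quantization the
bins cannot collide, since the worst-case quantization shift (≤ 3 per
channel, ≤ 6 on the sum) is smaller than the 40 − 16 gap. A trained
palette therefore separates the classes nearly perfectly while the best
axis-aligned box, found by exhaustive grid search (step 8 per bound,
reduced to cumulative-histogram sweeps plus a maximum-subarray pass so
the 6-dimensional search runs in seconds), cannot.

What passing these tests does **not** show: robustness to uneven
illumination, chromatic aberration, stain batch variation, JPEG
artifacts, out-of-focus regions, or textured backgrounds — none of
which the generator attempts. Synthetic results validate the machinery
(bookkeeping, conventions, formulas, determinism), not clinical
performance; on real material the visual-review-and-retrain loop
remains essential.

## Validation problem sizes

The test suite validates metrics against brute-force per-pixel oracles
on 1000 random mask pairs up to 64×64; palette recovery at target area
fractions of 1%, 10% and 30% on 256×256 fields across 5 seeds (reported
percent area within 1 point of the truth-mask fraction); two-class
ratio recovery within 5% relative error across 5 seeds; and the
palette-versus-box comparison on one 256×256 blended fixture. These
sizes were chosen as the smallest at which component statistics, color
coverage and the band construction are all non-trivial.

## Known limitations

* The palette is a lookup over quantized colors: it has no spatial
  model, so it cannot separate two classes that share colors (that is
  what morphology and size filters partially compensate for).
* No color-space transforms or stain deconvolution; the classifier
  works in raw RGB by design, matching the tool it reimplements.
* Whole-slide pyramid formats are out of scope; the unit of analysis is
  a field-of-view tile.
* The exact discretization and positive rule of the original
  interactive application are not published; this package's color map
  (uniform binning, majority-fraction rule) is a faithful reading of
  its description, not a bit-identical port.
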