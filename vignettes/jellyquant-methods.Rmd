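---
title: "Methods: detection post-processing and windowed quantification"
author: "jellyquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detection post-processing and windowed quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jellyquant)
```

## The problem

A deep object detector running over underwater video emits, for every
analyzed frame, a set of `(class, confidence, bounding box)` records.
For ecological monitoring the quantity of interest is not the boxes but
the *count timeline*: how many individuals of each species are present
as a function of time. The per-frame signal is noisy — translucent
bodies, changing luminosity, surface reflexes and unusual poses cause
sporadic missed detections, and the same conditions produce sporadic
low-confidence spurious boxes. `jellyquant` implements the stages that
turn raw detections into an evaluated detector and a stable count
timeline, independent of which detector produced them.

## Geometry and conventions

Boxes are axis-aligned rectangles `(xmin, ymin, xmax, ymax)` in
continuous pixel coordinates, origin at the top-left corner, with a
half-open `[min, max)` convention, so `area = (xmax − xmin)(ymax − ymin)`
is an exact pixel count and zero-area boxes are invalid (they raise an
error rather than propagating NaNs). PASCAL VOC XML files store 1-based
*inclusive* integer coordinates; `readVocAnnotation()` converts with
`xmin − 1, ymin − 1, xmax, ymax` and `writeVocAnnotation()` inverts this
and rounds to the nearest integer (the LabelImg tool writes integers).
The conversion is its own inverse on integer-aligned boxes, which the
test suite asserts by round-tripping.

Overlap is measured by intersection over union,
$\mathrm{IoU} = A_{\cap} / A_{\cup}$, symmetric, in `[0, 1]`, and equal
to 1 only for identical boxes. Confidences are stored as fractions in
`[0, 1]` and rendered as percentages wherever thresholds are reported,
matching how detector confidence thresholds are usually quoted.

## Non-maxima suppression

Duplicate detections of one animal are removed greedily: visit
detections by descending confidence and discard any remaining detection
whose overlap with an already-kept one exceeds the threshold. Two
choices deserve comment:

- **Overlap measure.** The suppression criterion is often described
  loosely as "intersection area greater than a threshold" of e.g. 40 %.
  An absolute area threshold expressed as a percentage is not
  well-defined, so the package reads this as IoU — the standard
  interpretation — and additionally offers
  intersection-over-minimum-area (`measure = "iomin"`), which is the
  other defensible reading and is stricter for nested boxes.
- **Class-agnostic.** Suppression ignores the class label: the
  geometric rationale (two jellyfish rarely appear superimposed)
  applies regardless of species, and a class-aware variant would let a
  misclassified duplicate survive.

Ties in confidence are broken toward the lower `xmin`, then `ymin`, so
output is deterministic. The default threshold 0.40 is deliberately
restrictive, appropriate when individuals rarely occlude one another.
Confidence filtering keeps detections with `confidence × 100 ≥
threshold`: the filter *deletes* strictly-lower confidences, so a
detection exactly at the threshold survives.

## Evaluation

Matching follows the PASCAL VOC protocol. Per frame and class,
predictions are assigned in order of descending confidence to the
unmatched ground-truth box with the highest IoU, provided IoU ≥
`thr_iou` (default 0.5). Each ground-truth box can be matched once;
duplicates and cross-class overlaps are false positives; unmatched
ground truth is a false negative. The `≥` in the IoU comparison is used
consistently (a boundary-exact overlap is a true positive).

Precision, recall and F1 follow their usual definitions with the
`0/0 = 0` convention. Average precision ranks all detections of one
class globally by confidence, matches them greedily in rank order, and
integrates the monotone (all-point, VOC2010-style) precision envelope
over recall; the classic 11-point interpolation is available behind a
flag since older comparisons use it. AP is undefined — an error, not a
silent 0 — for a class with no ground-truth objects.

The operating threshold `Cthr1` is chosen by an exhaustive sweep over
0–100 % in 1 % steps (101 evaluations). At each step the filtered
prediction set is re-matched from scratch, so true positives removed by
the filter correctly reappear as false negatives. Ties in F1 are broken
toward the *lowest* threshold: at equal F1 the lower threshold retains
more detections, and the choice is recorded in the report so it is
auditable.

The cross-validation splitter shuffles items once (seeded), forms `k`
folds with sizes differing by at most one, and pairs folds `(i, i+1 mod
k)` as the test set of run `i` — with `k = 10` each run tests on 20 % of
the data. Which two folds are paired is not dictated by anything
deeper; consecutive pairing keeps the scheme deterministic and every
fold appears in exactly two test sets.

## Quantification

Each analyzed frame yields an *information point*: the vector of
per-species detection counts after `Cthr2` filtering, timestamped
`frame / fps`. Frames with no surviving detections yield all-zero
points — representing "no animals" is essential, so the stream object
records the full set of analyzed frames, not just those with
detections.

Windows of `Wsize` consecutive points, advancing by `stride = Wsize (1 −
Wover)` points, are each reduced to a *resulting information point*.
Design choices, each genuinely open:

- **Per-species mode, not joint-vector mode.** The reduction takes the
  most occurring count *per species independently*. Monitoring output
  is consumed as per-species traces, and a joint mode discards
  information when two species fluctuate out of phase. (The similarity
  criterion below still compares the full vector, so per-species
  reduction is not a free pass.)
- **Tie-breaks.** A modal tie is resolved toward the previous resulting
  value for that species (temporal continuity — a tie should not flip
  an ongoing estimate), then toward the lower count (conservative
  against false alarms). Both rules are deterministic.
- **Timestamping.** Each resulting point is stamped at the window's
  final contributing frame. This is the causal choice — in real time
  the point can only be emitted once its last frame has been analyzed —
  and it makes the spacing between consecutive resulting points exactly
  `stride` frames, i.e. `T_RIpoint = Wsize (1 − Wover) / fps` seconds.
- **Correctness reference.** A resulting point is *correct* when its
  full count vector equals the manual ground truth *at the frame it is
  stamped on* (not a windowed reduction of the truth): the point claims
  to describe the situation at a determined time, so it is held to the
  truth at that time. *Similarity* is the percentage of correct
  resulting points.
- **Stride integrality.** Non-integer strides are rejected at
  configuration time rather than silently rounded; all standard
  combinations (`Wsize` 4/8/12 × `Wover` 25/50/75 %) give integer
  strides (1, 2, 3, 6, 9).

`Cthr2` is selected by the same 1 %-step exhaustive sweep, maximizing
Similarity, ties to the lowest threshold. Its optimum typically falls
well below `Cthr1`: windowing removes sporadic false positives, so
admitting low-confidence true detections is cheap. Window sizes
transfer across detectors of different speeds by inverting the stride
relation, `Wsize' = T_RIpoint · fps' / (1 − Wover)`; the inversion
asserts integrality within `1e-6` and reports the neighbouring integers
otherwise, since a silently rounded window size would no longer
preserve the stride duration. Whether suppression should also precede
quantification is not self-evident; the package applies NMS on the
quantification branch by default (`applyNms = TRUE` in `quantify()`),
treating both branches symmetrically, and makes it switchable.

## The synthetic scene and detector model

The simulator exists so that every stage — file formats, NMS,
evaluation, quantification — can be exercised end to end with known
ground truth. A scene is an immigration–death process per species:
arrivals are Poisson at `arrivalRate` per second, dwell times are
exponential with mean `dwellMean`, and the scene starts in the
stationary regime, so mean occupancy is `arrivalRate × dwellMean`
(Little's law, which the tests check by Monte Carlo). Individuals are
boxes with uniformly drawn side lengths performing a reflected Gaussian
random walk inside the frame.

Defaults describe the regime the algorithm is designed for: a
1920×1080 frame analyzed at 1.6 fps, five-minute scenes, one species,
`arrivalRate = 1/180` s⁻¹ and `dwellMean = 180` s — about one
individual in view at a time, entering or leaving every few minutes, a
slow count evolution typical of drifting medusae seen by a fixed
camera. Box sides 80–320 px and a 6 px/frame motion step give
slow-moving, well-resolved animals.

The detector model encodes the observed failure modes: each true box is
missed independently with `pMiss` (default 0.1), surviving boxes get
2 px Gaussian corner jitter and, with probability 0.02, a swapped
species label; spurious detections arrive as Poisson(`fpRate` = 0.05)
per frame with uniform random boxes. Confidences are Beta-distributed —
`Beta(8, 1.5)` for true positives (concentrated near 1) and
`Beta(1.5, 8)` for false positives (near 0) — reflecting that genuine
detections typically carry high confidence. All draws flow from one
seeded generator in a fixed order (per frame: per-object miss, jitter,
confusion, confidence; then the spurious count and per-spurious box,
confidence, class), so fixture bundles are byte-stable.

What the simulator deliberately does **not** emulate: images (no
rendering, turbidity or illumination model — failure modes are injected
at the detection level, not caused optically), occlusion-correlated
misses (misses are i.i.d., while real misses cluster in time),
detector-specific confidence calibration, and within-track confidence
correlation. Passing tests therefore demonstrate the correctness and
noise-rejection of the *algorithms* under the stated error model, not
the field performance of any particular detector.

## Problem sizes and numerical tolerances

The test suite validates NMS against an `O(n²)` greedy oracle on 500
random frames, AP against an exhaustive per-rank re-matching staircase
oracle on instances of up to ten detections, the IoU kernel against a
grid-rasterization oracle (exact for integer boxes), and both
confidence sweeps against independent exhaustive loops. The
quantification pipeline is exercised on 10-minute single-species scenes
(960 analyzed frames) over 20 seeds, where the `Cthr2` sweep plus
(12, 25 %) windowing holds mean Similarity above 95 % under the default
error model; 200-replicate experiments check that larger windows never
hurt average Similarity under i.i.d. errors on constant-count streams.
These sizes keep the full suite around a minute on one core while
leaving the Monte-Carlo assertions three-standard-error margins.

Floating point is handled at the edges where it matters: stride
integrality uses a `1e-9` tolerance, window-size inversion `1e-6`, and
confidence thresholds compare `confidence × 100 ≥ threshold` directly
(IEEE multiplication by 100 is exact enough that boundary cases like
0.11 vs 11 behave as intended, which the tests pin down).

## Known limitations

- Similarity is an exact-vector-match criterion: it does not
  distinguish near-misses (count off by one) from gross errors, and at
  count transitions the windowed mode necessarily lags the truth by up
  to half a window, bounding attainable Similarity on scenes with
  frequent turnover.
- Counts are per frame; there is no tracking, so the package cannot
  report *how many distinct* individuals passed through, only
  instantaneous abundance.
- NMS is greedy, not globally optimal, matching standard practice.
- The evaluation assumes one annotation file per frame and within-frame
  matching only; it does not implement COCO-style AP@[.5:.95] or
  between-species confusion matrices.
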