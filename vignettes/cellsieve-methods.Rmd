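---
title: "cellsieve: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cellsieve: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellsieve)
```

## The problem

Differential counting of nucleated cells on a bone-marrow smear — and,
analogously, mitotic-figure screening in tumor sections — requires finding
and typing thousands of cells of many morphologically similar classes on a
gigapixel whole-slide image (WSI). Manual annotation of such slides is never
exhaustive: experts label a limited set of easily identifiable, scattered
cells. Training an object detector on such *partially annotated* data has a
specific failure mode: every unlabeled true cell that ends up in the
negative (background) sample pool teaches the model that cells are
background.

cellsieve implements the detector-agnostic computations that address this
setting around a cascade detector: sample selection with a dual-layer
negative filter, soft attention weights, single- and multi-class
non-maximum suppression, overlap-gated augmentation with
histogram-specification normalization, a data-oriented learning-rate
schedule, coordinate mapping between pyramid levels, and clinical
reporting. The detector itself (backbone, region-proposal network, training
loop) is out of scope; the package consumes and emits boxes, scores and
weights in COCO-style JSON.

## Geometry conventions

Boxes are axis-aligned rectangles in 0-based, half-open pixel coordinates
`[x_min, x_max) × [y_min, y_max)`, so area is `(x_max − x_min)(y_max −
y_min)` and an integer box of side *s* contains exactly *s²* pixels. The
Jaccard index (IoU) ϖ of two boxes is computed on continuous geometry; for
integer boxes this agrees exactly with counting member pixels, which is how
the test suite validates it against an enumeration oracle. The half-open
convention was chosen because it composes cleanly under scaling and avoids
the ±1 area bugs of closed-interval pixel conventions; nothing else in the
package depends on the choice.

Two-level analysis (locate regions of interest at low magnification,
analyse at high magnification) is supported by `level_map()`/`map_box()`,
which multiply or divide coordinates by per-axis scale factors ≥ 1.
Round-trips are exact for integer scales and within one pixel otherwise. No
margin is added around mapped regions; if an upstream ROI model needs
context padding, it should pad before mapping.

## Cascade sampling and the dual-layer negative filter

A cascade detector trains `Z` sample classifiers against increasing overlap
thresholds

φ_z = φ₁ + (z − 1)·ρ, z = 1…Z,

with defaults φ₁ = 0.5, ρ = 0.1, Z = 3, giving thresholds 0.5, 0.6, 0.7.
At stage z a candidate with reference overlap ϖ is positive iff ϖ ≥ φ_z
(all comparisons in the package are boundary-inclusive, following the
as-printed inequalities). Because thresholds increase, positives shrink
monotonically across stages.

Under partial annotation the negatives of the final stage are contaminated:
proposals sitting on unlabeled true cells record near-zero overlap against
the *annotated* reference and look like background. The dual-layer filter
splits the stage-Z negatives at a second, low threshold φᵢ (default 0.1):
negatives with ϖ ≥ φᵢ are kept as *refined negatives* (hard background
near a labeled cell — informative), negatives with ϖ < φᵢ are moved to an
*ignored* class with weight zero (they may be unlabeled cells — unsafe to
train on). The filter applies to the final stage only, where the classifier
that produces the deployed scores is trained; `refine_all_stages = TRUE`
exists for ablation.

This is a deliberate asymmetry: the filter cannot *identify* unlabeled
cells, it only refuses to swear they are background. The simulator (below)
is used to measure the effect: the fraction of refined negatives that sit
on an unlabeled true object is compared with the same fraction among
unrefined negatives.

Soft-sampling weights let every candidate contribute to the loss with an
attention weight reflecting its reliability. The exact weighting function
is detector-specific, so `soft_weights()` takes a pluggable
`weight_fn(overlap, score)` with range (0, 1]. The packaged default is a
linear ramp

w(ϖ) = min(1, w_min + (1 − w_min)·ϖ/φ₁), w_min = 0.1,

chosen as the simplest function that satisfies the required behavior —
everything contributes, low-overlap background contributes least, weight is
monotone in overlap, positives get exactly 1. The floor `w_min = 0.1` is a
package decision (a tenth of a positive's attention), not a calibrated
constant; trainers with their own weighting should supply it via
`weight_fn`.

## Suppression: single-class vs multi-class

Detections carry a per-class probability vector; the argmax class and its
probability drive suppression, with the full vectors carried through for
reporting. After thresholding at the classification confidence ϱ (default
0.5, inclusive), two greedy suppressors are available, both visiting
detections in descending score order with ties broken toward the lower
input index:

* `scnms()` suppresses within each class independently: a detection is
  pruned iff it overlaps an already-kept *same-class* detection at
  Jaccard ≥ η (default 0.3). A single cell can therefore survive with
  several contradictory class labels.
* `mcnms()` runs one greedy pass over all classes jointly, so no two kept
  boxes overlap at ≥ η. This is the "no contradictory prediction"
  guarantee, and it is assertable: the maximum pairwise Jaccard of any
  `mcnms()` output is < η by construction.

Both are idempotent. `brute_force_suppression()` is an independent oracle
(repeated extraction of the maximum, explicit conflict deletion, guarded to
≤ 12 boxes) used by the tests to validate both suppressors exhaustively on
randomized instances.

One subtlety is worth stating because it is easy to assume otherwise: the
multi-class kept set is *typically but not always* a subset of the
single-class kept set. Greedy selection deletes suppressed boxes, and a
cross-class suppression can delete precisely the box that would have
suppressed a third, same-class box — which then survives multi-class
suppression despite being removed by the single-class pass. The unit suite
contains a minimal three-box counterexample. The contradiction-freedom
guarantee is unaffected.

## Augmentation and normalization

Patches are worth augmenting only if they contain labeled signal. For each
tile z of a `tile_grid()`, `positive_fraction()` computes |h ∩ z| / |z|
where h is the union of annotation boxes (boxes, not pixel masks — the
package has no access to masks), and a tile is selected iff the fraction is
> 0.

`augment()` emits, independently per operation: rotations at
5°, 10°, 15°, 20°, 25° and 90°, 180°, 270°; horizontal and vertical mirror
copies; and photometric-jitter copies with contrast and saturation factors
drawn uniformly from 1 ± 0.2 and brightness offsets from ± 0.125 on a
[0, 1] scale. The rotation set reads an ambiguous recipe ("five times in 5°
steps, plus right-angle increments") in the only way that makes both halves
meaningful; it is configurable if a user wants a different set. Corners
exposed by non-right-angle rotations are filled with the patch's
per-channel median (a neutral background estimate; the choice is
documented, not canonical). Jitter copies default to 3 per patch;
`compose = TRUE` applies jitter on top of each geometric copy instead.
Everything is deterministic given the spec seed, and
`map_augmented_boxes()` applies the same geometric map to annotation
corners so augmented patches keep consistent annotations.

Normalization is histogram specification: each channel is mapped through
its empirical CDF and the inverse reference CDF (quantile matching). The
packaged reference (`default_reference_histogram()`) is a synthetically
generated, natural-image-like smooth RGB distribution shipped as a
plain-text table — the package deliberately does not depend on any external
image corpus; users normalizing against their own cohort should fit a
reference with `fit_reference_histogram()`. Degenerate rule: a constant
channel has no usable CDF and maps to the reference median. With 256
reference levels, self-specification is the identity up to 1/255, and the
output's empirical CDF tracks the reference within Kolmogorov–Smirnov
distance 0.02 on continuous-noise images of 128 × 128 and larger (asserted
in the tests).

## Adaptive learning-rate schedule

With I training images of w × h pixels cut into q × q unit patches, the
training set holds N = I·⌈w/q⌉·⌈h/q⌉ patches. The adaptive schedule drops
the learning-rate multiplier by α (default 0.1) after every `step_size`
iterations:

r(Λ) = max(0, 1 − ⌊Λ/step⌋·α), step = N/α.

The multiplier starts at 1, is piecewise constant, takes at most 1/α + 1
distinct values, and is clamped at 0 (the unclamped form goes negative
after 1/α steps; the clamp is a documented package decision). The printed
form of the step formula is typographically ambiguous between N/α and N·α;
the N/α reading — a decay horizon proportional to the amount of data, which
is the stated motivation for the schedule — is the default, and
`interpretation = "times_alpha"` provides the other. The conventional
fixed-milestone schedule (10% reduction at 160k/240k iterations) is
available via `fixed_step_schedule()` as a comparison baseline.

## Reporting

`match_detections()` matches greedily by descending detection score at
IoU ≥ 0.5 (configurable), one-to-one: each detection claims the unmatched
annotation it overlaps best. Detection protocols rarely publish their
matching rule; greedy-by-score is the common convention and is stated here
as the package's. Two regimes are computed side by side: class-agnostic
("was the cell found") and class-required ("found and correctly typed").
Confusion matrices are built from the class-agnostic pairs — agnostic
matching is what allows a cell found under the wrong type to land off the
diagonal — and are row-normalized to percentages.

Per-class accuracy needs a true-negative count, which detection benchmarks
do not define. The package uses a one-vs-rest reading over the universe of
resolved instances (matched pairs + missed annotations + unmatched
detections); this is an interpretation, clearly labeled, and not a
replication of any published accuracy. The same applies to `pr_auc()`
(interpolated precision, area over the score ranking).

Cohen's κ = (p_o − p_e)/(1 − p_e) quantifies chance-corrected agreement
between two raters, with the conventional bands: ≤ 0.20 poor, 0.21–0.40
fair, 0.41–0.60 moderate, 0.61–0.80 good, 0.81–1.00 excellent. When both
raters are constant and identical, p_e = 1 and κ is returned as 1 with a
warning (agreement is perfect but unquantifiable against chance).

`ndc_report()` turns classified detections into the differential-count
readout: per-type counts and percentages, with the standard adequacy rule
that at least 500 cells must be counted (inclusive), and an exclusion list
for non-countable categories such as megakaryocytes.

## The simulator

`simulate_field()` generates the study conditions every property above is
measured under: a 512 × 512 field with 40 elliptical cells of 4 classes
(semi-axes 8–20 px, pairwise Jaccard of true boxes bounded below 0.3), a
configurable unlabeled fraction u, 4 jittered proposals per cell
(translation/scale jitter 0.15) plus 20 background proposals, proposal
scores equal to true overlap plus Gaussian noise (sd 0.1, clipped to
[0, 1]), and detections with probability vectors putting 1 − 0.1 on the
true class. These defaults are one scientist's notion of a realistic,
moderately cluttered microscope field at analysis magnification — dense
enough that suppression and matching are non-trivial, small enough that a
full suite of many hundreds of fields runs in seconds. All randomness flows
from the single spec seed through a private RNG stream; global RNG state is
untouched, and identical seeds give bit-identical fields.

What the simulator does *not* emulate: real cytomorphology (chromatin
texture, lineage-specific shape), stain variation between labs, touching
and overlapping cells beyond the overlap bound, annotation errors, and the
long-tailed class imbalance of real marrow. Consequently, passing tests
demonstrate the correctness of the computations and the direction of the
dual-layer filter's effect under controlled contamination — not clinical
performance on real slides.

`simulate_two_level()` wraps the same generator in a low/high magnification
pair so the coordinate-mapping contract (high-magnification annotations map
back inside their ROI) is testable end to end.

## Problem sizes and numerical choices

The shipped suites use: 1000 random instances of ≤ 10 boxes and ≤ 5 classes
for the suppression oracle, 1000 random integer box pairs for the Jaccard
oracle, 50 simulated fields at u = 0.5 (and 0.2) for the contamination
property, 128 × 128 continuous-noise images for the normalization bound,
and n = 10 000 shuffled labels for the κ null check — sizes at which every
property is measured stably while the whole suite completes in about a
minute on one CPU. Tie-breaks are everywhere deterministic (lowest index
wins), thresholds are inclusive, and degenerate inputs (empty candidate
sets, empty fields, constant channels, zero detections) return well-defined
empty or flagged results rather than errors wherever the operation is
total.

## Known limitations

* The package computes sampling weights and assignments but does not train
  anything; claims about end-detector quality are outside its scope.
* Matching, accuracy and PR-AUC conventions are explicit package decisions
  where the field's literature is silent; numbers computed under them are
  not comparable to publications that chose differently.
* Histogram specification is the only normalization offered (no
  stain-deconvolution methods).
* The MCNMS-in-SCNMS nesting caveat above: downstream code must not assume
  the multi-class kept set is a filtration of the single-class one.
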