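---
title: "Evaluating pulmonary-nodule CAD detections: matching rules, metrics and error analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating pulmonary-nodule CAD detections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noduleval)
```

## The evaluation problem

A CAD algorithm for pulmonary nodules emits, per CT case, a set of
predicted findings, each a stack of per-slice axis-aligned bounding boxes.
The reference standard is a set of expert-annotated nodules, each likewise
a multi-slice box stack carrying a type label (six categories: solid,
part-solid, pure ground-glass, calcified, pleural, pleural calcified) and
long/short/average diameters in mm. Scoring an algorithm requires a
*mark-labeling* rule — a criterion deciding when a predicted mark and a
reference nodule are the same finding — plus an assignment procedure that
keeps the pairing one-to-one. Different labs use different rules, and the
choice measurably changes recall, precision and F1; this package makes the
rule an explicit, switchable parameter so results become comparable.

## Matching model

Coordinates are 0-based pixel indices with half-open boxes
`[x_min, x_max) × [y_min, y_max)`; the box center is the midpoint of each
axis. Pixel spacing is per-case and per-axis (`c(row, col)` mm), so mm
distances apply the column spacing to x-differences and the row spacing to
y-differences. Slice correspondence is exact: a reference slice is only
ever compared with a predicted box carrying the same `slice_index`.
Cross-slice pairing would need a z-tolerance no convention defines, and
slice indexing already constrains the axial position; distances are
therefore purely in-plane.

Per shared slice, the three rules are:

* **center hit** — the predicted box center lies in the *closed* reference
  box; a center exactly on the boundary counts as inside. The region is
  the bounding box, not the annotated polygon (polygons are optional in
  the schema).
* **center distance** — the center distance in mm is *strictly* less than
  the reference nodule's adaptive radius, `max` over its slices of
  `(long + short)/4`. The threshold is per-nodule, not global: a 3 mm
  nodule demands ~1.5 mm localization, a 20 mm nodule tolerates ~10 mm.
* **area overlap** — the intersection area divided by the *reference* box
  area is *strictly* greater than the threshold (default 0.5). The
  denominator is deliberately the reference, not the union: a prediction
  that over-covers the nodule is not penalized by this rule (precision
  penalizes box inflation globally instead).

Strict inequalities are a documented bit-exact choice: a distance exactly
at the radius, or an overlap of exactly 0.5, fails. Ties at a threshold
are rare in real data but common in tests, and an unambiguous convention
makes results reproducible across implementations.

A prediction matches a nodule if *any* shared slice succeeds; zero shared
slices is an ordinary failure, never an error.

## Greedy one-to-one assignment

Per case, reference nodules enter a queue in a canonical *matching order*:
descending largest-slice box area, ties by ascending `nodule_id`
(configurable to file order or id order via `match_order`). Each reference
takes the best still-unmatched succeeding prediction and removes it from
the pool; references with no candidate are FN, predictions left at the end
are FP. Largest-first ordering prevents a small neighbour from consuming
the prediction that localizes a large nodule. The best candidate is chosen
by tie-break score:

* center distance rule — the smallest succeeding center distance;
* area overlap rule — the largest overlap fraction;
* center hit rule — the smallest in-plane distance between the reference's
  *largest slice* (maximal box area, ties to the lowest slice index) and
  the candidate's box at that slice, or, if the candidate has no box
  there, its box on the nearest slice. This interpretation (2-D distance,
  candidate slice resolved as stated) is one of several readings of
  "distance to the largest slice"; it is fixed here, tested, and
  documented rather than left implicit.

Exact score ties fall back to the lowest `pred_id` — determinism again.
The procedure is intentionally greedy, not optimal (Hungarian) assignment:
it mirrors how marks are adjudicated in sequential reading, and the test
suite verifies it against an independent brute-force walk of the same
queue discipline on thousands of random small cases.

AUTs that only claim a subset of the six types can be scored with
`type_scope`: out-of-scope references are removed from TP/FN accounting,
and predictions that would have matched them are dropped rather than
counted FP (the algorithm is neither credited nor penalized outside its
claim). The default is no filtering, since scoring scope handling differs
between labs; both behaviours are available and logged in the audit.

## Metrics and aggregation

Counts are pooled over cases within an AUT before ratios are taken
(micro-averaging); recall, precision and F1 use the 0-when-undefined
convention so degenerate inputs (an AUT that outputs nothing) still
produce a full metric set. Across AUTs the package reports mean ± sample
SD (n−1); with ten algorithms the sample SD is the standard choice.
Percentage-point rule deltas are rounded to two decimals on the percent
scale. The relative difference of TP counts against a baseline rule,
`RD = (TP_rule − TP_base)/TP_base`, is undefined (an error) for a zero
baseline.

Miss rates are FN/n_ref per stratum (type, or type × size bin over
average diameter with left-closed bins `[0,4), [4,6), [6,10), [10,∞)` mm
— printed bin notation in the field is inconsistent, and a partition of
the line is mandatory, so boundary diameters go up). Strata without
references are `NA`, never 0. The most-missed heatmap credits, per AUT and
bin, the argmax-miss-rate type among defined cells; exact ties credit all
tied types and are counted in a `ties` column, so per-bin counts sum to
the AUT count plus ties.

## Statistical comparison of rules

Per metric, the per-AUT values under each rule form groups compared by
classical one-way fixed-effects ANOVA (`stats::oneway.test`, equal
variances) and pairwise two-sided Student pooled-variance t-tests
(`stats::t.test`), labelled `**` (p ≤ 0.01), `*` (p ≤ 0.05), `ns`
(p > 0.05). No multiplicity correction is applied across the three
pairwise tests — the convention in the reports this package standardizes —
and the defaults deliberately treat the groups as independent even though
the same AUT panel underlies all rules; `paired = TRUE` and `welch = TRUE`
switches are provided for analysts who prefer the paired or
unequal-variance versions. When all observations are identical the ANOVA
F is defined as 0 with p = 1; a t-test between two different constants is
flagged `degenerate` rather than silently producing infinity.

## Annotation quality control

Qualification scores a candidate annotator against an expert panel:
detection precision/recall per-nodule via the same matching machinery
(center hit by default), plus the mean Dice coefficient
`2|A∩B|/(|A|+|B|)` over matched pairs, areas summed over each region's
slices and intersections over shared slices, computed on bounding boxes.
The gate is strict — all three scores must *exceed* 0.8; exactly 0.8
fails.

Consensus merging takes exactly three readers' back-to-back annotations of
a case, pairs detections between every two readers by one-to-one matching,
groups pairs transitively, and accepts a group as consistent only when it
holds one nodule per reader with all three pairwise matches present.
Consistent groups merge into per-slice enclosing-box unions (diameters by
per-slice maxima); every slice of any other detection is flagged for
senior review. Arbitration itself remains a human act — the package only
produces the flag list.

## Synthetic data: what it emulates, and what it does not

The generator reproduces the *composition* of a realistic multi-hospital
chest-CT test set: ~10.3 nodules per case (Poisson), type proportions
42.66 / 5.06 / 19.58 / 7.40 / 23.06 / 2.24 % and size-bin proportions
69.91 / 19.63 / 7.28 / 3.18 %, in-plane spacing uniform in 0.5–0.9 mm.
Slice thickness is drawn uniformly from 0.625–2.5 mm — real thickness
distributions are multimodal over a handful of protocol values, but the
evaluation machinery is insensitive to that refinement, so a uniform draw
keeps the generator simple. Within-bin diameters are log-uniform (only bin
proportions are specified anywhere; log-uniform keeps small nodules
dominant within the wide bins), truncated at 30 mm since every nodule
definition caps the long diameter at 3 cm, with a 2 mm annotation floor.
Multi-slice extent is `round(diameter / slice_thickness)` slices with an
elliptic in-plane taper anchored so the central slice carries the full
diameter; long/short diameters split symmetrically around the tapered
diameter, so `average_diameter = (long+short)/2` on the largest slice.
Nodules are placed with disjoint 2-D footprints by rejection sampling (100
tries, then the diameter is halved; a nodule that still cannot be placed
is skipped).

The AUT simulator detects each nodule independently with probability
`sensitivity[type, bin]`, then perturbs the copied box stack: Gaussian
center jitter (SD = `center_jitter_sigma` × the nodule's matching radius,
per axis), log-normal size scaling, and random truncation of boundary
slices. False positives are Poisson per case, placed with centers outside
every reference footprint dilated by its matching radius plus the largest
FP half-width — this keeps configured sensitivities identifiable under
*all three* rules, because a spurious mark can then never be absorbed as a
match. Each run is reproducible from a single seed.

What passing tests on this data do **not** show: real CT appearance
effects (the generator has no image content, so nothing links "pure
ground-glass" to low contrast — per-type behaviour is whatever the
sensitivity map dictates), reader variability in diameters, overlapping or
attached nodules, or 3-D detectors (a 3-D AUT's output must be flattened
to per-slice boxes upstream). The generator validates the *accounting*,
not the radiology.

## Numerical and degenerate-input choices

* Duplicate `(case, id, slice)` rows, degenerate boxes, non-numeric
  coordinates and unknown type labels are hard errors with file line
  numbers; annotation gaps across slices are tolerated (only strict slice
  ordering is enforced).
* An empty prediction CSV is a valid empty set; predictions for a case
  absent from the reference standard warn and count as FP in their own
  case universe.
* `aggregate_over_auts` refuses a single value (no sample SD); metric
  conventions at zero denominators are 0, documented.
* All tie-breaks (matching order, candidate score, largest slice,
  merged-nodule naming) resolve deterministically, so two runs over the
  same inputs are byte-identical.

## Limitations

* The greedy pairwise matching used in consensus merging is not exactly
  symmetric for pathologically overlapping reader annotations; permutation
  invariance is guaranteed (and tested) for well-separated findings, which
  is the realistic regime.
* The matching-order definition, the center-hit tie-break and the
  strict-inequality thresholds are reasonable fixed conventions, not
  uniquely correct readings; all are configurable or documented so a lab
  can state exactly what it ran.
* Rule thresholds (0.5 overlap; adaptive radius) are empirical
  conventions; the package compares rules but cannot say which matches a
  clinical use case — that depends on the downstream task (localization
  for intervention favours center distance, contouring for radiotherapy
  favours area overlap).

## Problem sizes in the shipped checks

The test suite exercises the matcher against a brute-force oracle on
1000+ random small cases per rule, accounting identities on a further
1000, and parameter recovery on a 194-case (~2000-nodule) ten-AUT
simulation at center jitter 0.15 — sizes chosen so the whole suite runs in
a few minutes on one CPU while keeping binomial error bands tight enough
to detect real defects. `scripts/acceptance.R` re-runs the pipeline on a
100-case, ten-AUT study and writes every headline quantity it computes as
JSON; all randomness derives from its `--seed` argument.
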