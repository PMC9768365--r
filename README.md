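# noduleval

Standardized, third-party-style performance evaluation of computer-aided
detection (CAD) algorithms for pulmonary nodules on chest CT.

When several vendors' nodule-detection algorithms are tested against the
same expert-annotated reference standard, the single most consequential —
and most often under-specified — choice is the *mark-labeling* rule: the
criterion that decides whether an algorithm's predicted bounding box
matches a reference nodule. `noduleval` implements three such rules and
everything around them, so that a testing lab can score any number of
algorithms under test (AUTs) against one reference standard, compare the
rules themselves, and analyze where the algorithms fail.

## What it computes

**Matching.** A reference nodule is a stack of per-slice bounding boxes
with long/short diameters; a prediction is a stack of per-slice boxes. A
prediction matches a reference when at least one shared slice succeeds
under the selected rule:

- **center hit** — the predicted box center falls inside the reference box
  (closed region);
- **center distance** — the in-plane center distance (mm, per-axis pixel
  spacing applied) is strictly below an adaptive per-nodule radius
  `r = max over slices of (long + short) / 4`;
- **area overlap** — `|pred ∩ ref| / |ref|` strictly exceeds a threshold
  (default 0.5).

Assignment is greedy and one-to-one: reference nodules are visited in a
deterministic order (largest first by default), each takes its best
still-unmatched candidate (smallest center distance, or largest overlap
fraction), and leftover predictions become false positives. For `TP`,
`FP`, `FN` counts the package reports recall = TP/(TP+FN), precision =
TP/(TP+FP) and F1, pooled over cases per AUT, then mean ± SD across AUTs.

**Rule comparison.** Per-rule means are compared as percentage-point
deltas; per-AUT true-positive counts as relative differences against a
baseline rule, RD = (TP_rule − TP_baseline) / TP_baseline; and per-AUT
metric values by one-way ANOVA plus pairwise t-tests with `ns` / `*` /
`**` labels (p > 0.05, ≤ 0.05, ≤ 0.01).

**Error analysis.** Per nodule type (solid, part-solid, pure ground-glass,
calcified, pleural, pleural calcified), the miss rate FN/n_ref; refined by
average-diameter bins [0,4), [4,6), [6,10), [10,∞) mm; and a "most-missed"
heatmap counting, per bin, how many AUTs miss each type the worst.

**Annotation QC.** Annotator qualification against an expert panel
(strict gate: precision > 0.8, recall > 0.8, Dice > 0.8) and three-reader
consensus merging with per-slice flags for senior arbitration.

**Synthetic data.** A generator for reference datasets with a realistic
type/size composition and an AUT simulator with controllable per-type
sensitivity, center jitter, box-size error and false-positive load — the
whole pipeline is testable without patient data.

## Worked example

```r
library(noduleval)

cases <- generate_reference_dataset(dataset_spec(n_cases = 20, seed = 7))
profiles <- list(
  autA = aut_profile(sensitivity = c(solid = 0.7, part_solid = 0.8,
                                     pure_ground_glass = 0.45, calcified = 0.75,
                                     pleural = 0.55, pleural_calcified = 0.7),
                     center_jitter_sigma = 0.15, fp_per_case_mean = 3, seed = 71),
  autB = aut_profile(sensitivity = 0.6, center_jitter_sigma = 0.25,
                     box_scale_sigma = 0.2, fp_per_case_mean = 6, seed = 72),
  autC = aut_profile(sensitivity = 0.75, center_jitter_sigma = 0.1,
                     fp_per_case_mean = 2, seed = 73))
panel <- simulate_aut_panel(cases, profiles)

evaluate_aut(cases, panel$autA, "center_distance")$metrics
#> <metric_set TP 137 FP 59 FN 65 | recall 0.6782 precision 0.6990 F1 0.6884>

compare_rules(cases, panel)
#> <rule_comparison>
#> Per-rule mean +/- SD (%):
#>             rule recall_mean recall_sd precision_mean precision_sd f1_mean f1_sd
#>       center_hit       66.17     9.025          67.97        15.05   66.97 11.99
#>  center_distance       66.17     9.025          67.97        15.05   66.97 11.99
#>     area_overlap       65.18    10.645          67.06        16.51   66.02 13.53
#> Pairwise mean differences (percentage points):
#>           rule_a          rule_b recall precision   f1
#>       center_hit center_distance   0.00      0.00 0.00
#>       center_hit    area_overlap   0.99      0.91 0.95
#>  center_distance    area_overlap   0.99      0.91 0.95
#> recall: ANOVA p = 0.9894 [ns]
#> ...

error_analysis(cases, panel)$by_type[, c("type", "n_ref", "mean", "sd")]
#>                type n_ref  mean     sd
#> 1             solid    87 0.337 0.1362
#> 2        part_solid     4 0.417 0.2887
#> 3 pure_ground_glass    48 0.382 0.0636
#> 4         calcified    18 0.241 0.0849
#> 5           pleural    36 0.361 0.1470
#> 6 pleural_calcified     9 0.185 0.2313
```

Reading the output: the three simulated AUTs detect ~66% of reference
nodules under the center rules; the area-overlap rule is (as expected)
the harsher criterion, costing about one percentage point here because the
simulated boxes are only mildly mis-sized; with just three AUTs none of
the rule differences reach significance. The error analysis shows the
per-type FN fractions averaged over the panel.

The same operations are available from the shell via
`inst/scripts/noduleval.R` (subcommands `simulate`, `evaluate`,
`compare-rules`, `error-analysis`), reading/writing the package's CSV
schemas (`?read_reference_csv`).

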