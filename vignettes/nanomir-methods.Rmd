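---
title: "Methods: the nanomir miRNA biomarker-discovery pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the nanomir miRNA biomarker-discovery pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanomir)
```

## The problem

Digital molecular counting on the nCounter platform yields integer counts for
roughly 800 miRNA probes per sample lane, alongside negative ligation controls
(probes with no target, whose counts estimate chemical background) and
non-human spike-in probes added at fixed amounts. A typical biomarker study
profiles two small groups (cases and controls) in one or two blood fractions —
the cellular fraction (PBMCs) and plasma extracellular vesicles (EVs) — and
asks which miRNAs differ between groups and how well each discriminates the
groups at the individual level.

`nanomir` implements that workflow as a deterministic, fully auditable
pipeline: every stage emits a filter log recording which samples or probes it
removed and why, so every headline number (samples analysed, robust probes,
significant hits) is reconcilable from the logs.

## Stages and their parameters

### Background threshold

All Negative-class counts of a fraction are pooled across samples; the
threshold is their geometric mean plus two sample standard deviations
(`background_threshold()`, `n_sd = 2`). Zeros are replaced by 1 before the
geometric mean only, the digital-count platform convention; the SD is taken on
the unreplaced pooled counts with the n − 1 denominator. One pooled threshold
is computed per fraction rather than per sample, because the quantity is a
property of the assay chemistry, not the lane. Raw counts at or above the
threshold count as detected; counts strictly below are censored — retained in
the matrix for inspection but excluded from all downstream statistics
(`apply_normalization()`).

### Normalization

Per-sample factors equalize the geometric mean of a reference probe set
across samples (`reference_factors()`): for the cellular fraction the
reference is the `top_n = 100` endogenous probes with the highest mean raw
count (ties by probe id), selected on raw means since factor computation
precedes normalization; for the EV fraction, whose endogenous content is too
sparse to furnish a stable top set, the reference is the spike-in probes.
Each factor is `mean(reference geomeans) / (sample's reference geomean)`, so
scaling a lane by *c* scales its factor by 1/*c* and post-normalization
reference geomeans agree to within floating-point error (tested to a relative
1e-9).

### Filter cascade

* **RIN gate** (`filter_by_rin()`, `min_rin = 7`, strict): applies to
  cellular-fraction samples only; no RNA-integrity control is applicable to
  EV total RNA, so EV samples pass unconditionally.
* **Low-coverage samples** (`drop_low_coverage_samples()`,
  `max_below_frac = 0.40`, boundary inclusive): a sample is dropped when 40%
  or more of the endogenous probes are below threshold.
* **Robust probes** (`robust_probe_filter()`, `min_frac = 0.75`, inclusive):
  a probe is kept when detected in at least 75% of samples of *either*
  group. The either-group rule deliberately retains probes expressed in only
  one condition.

### Outlier adjustment

`chauvenet_filter()` implements a single-pass acceptance band: mean ± 2
sample SDs, computed once on the input; values strictly outside are removed,
with no re-iteration. The band width (`n_sd = 2`) and the single pass follow
the variant used in this field rather than the classical Chauvenet rule
(expected-count < 0.5 under the normal tail), which is intentionally not the
default. The bare operation applies no retention floor — {0×9, 10} removes
the 10 and keeps nine zeros — while the differential-expression stage applies
a configurable per-group floor (`chauvenet_min_keep = 10`), mirroring the
design target of never testing fewer than 10 samples per group: if removal
would breach the floor, the most extreme values go first and removal stops at
the floor.

### Differential testing

For each robust probe the per-probe sample universe is the set of samples in
which the probe is detected, so per-group n varies by probe. Each probe is
tested with `shapiro_branch_test()`: a Shapiro-Wilk screen per group
(`shapiro_alpha = 0.05`), Student's t (equal variance) when both groups pass,
Mann-Whitney otherwise. Two design points deserve explanation:

* **Screen minimum.** The screen is only consulted when a group has at least
  `shapiro_min_n = 4` values. At n = 3 Shapiro-Wilk has essentially no power
  — three points almost never contradict normality (e.g. W = 1 for any three
  equally spaced values) — so letting it choose the t branch there would be
  arbitrary; smaller groups default to the rank test.
* **Branch fixation under re-testing.** Probes whose first-pass p falls below
  `p_trend = 0.1` are re-tested after the per-group outlier adjustment, and
  the adjusted result is reported. The re-test *keeps the branch chosen on
  the full detected data*: trimming tails makes any sample look Gaussian, and
  re-running the screen on trimmed values would systematically switch
  candidates to a t test with a shrunken SD, inflating false positives. The
  test is a property of the probe's full data; the adjustment refines values,
  not the distributional call.

The Mann-Whitney branch uses the exact null distribution when both groups
have at most 15 values and there are no ties, and the normal approximation
with continuity and tie correction otherwise. Significance tiers are
`significant` (p < 0.05) and `trend` (0.05 ≤ p < 0.1), driven by unadjusted
p values; a Benjamini-Hochberg column is emitted as supplementary output but
never drives tiers, matching the two-tier screening design this pipeline
reproduces.

Percent change is asymmetric by design: over-expression is reported relative
to the control level, under-expression relative to the case level —
`100·(control − case)/case` — which is the only convention under which
under-expression can exceed 100%. Location summaries are means under the t
branch and medians under the rank branch.

### Diagnostics

`roc_auc_ci()` computes the empirical AUC as the Mann-Whitney U statistic
over n₁·n₂ pairs with ties counting ½, orients the marker so AUC ≥ 0.5, and
attaches a 95% confidence interval from the DeLong placement-value variance
estimator, truncated to [0, 1]. DeLong rather than bootstrap: deterministic,
fast, and exactly testable.

`cluster_leaf_order()` orders probes for heatmap display using
1 − Spearman rank correlation as distance and centroid linkage via the
Lance-Williams update. Centroid linkage over a correlation distance is
mathematically improper — merge heights can invert — and the inversions are
recorded in the result rather than silently reordered, since this combination
is what the field's heatmap tooling offers. Leaf order is a deterministic
left-before-right traversal with the earlier-created cluster on the left;
constant rows receive distance 1 to everything, with a warning.

## The synthetic-data generator

`simulate_counts()` draws an overdispersed count panel from a
negative-binomial (Poisson-gamma) model: per-probe expected counts come from
a log-normal baseline, a per-sample log-normal technical scale factor
perturbs all probes of a lane, and planted differentially expressed probes
have the case-group mean multiplied (up) or divided (down) by a fold drawn
from `fold_range`. Negative controls are low-mean, group-independent draws;
spike-ins are high-mean, low-variance draws sharing only the lane scale.
Every operation consumes its own RNG stream seeded by (seed, operation-name
hash), so adding operations never shifts existing draws and the same seed is
bit-reproducible.

Defaults emulate the study conditions this pipeline was built around: 798
endogenous probes, 8 negative controls, 6 spike-ins, 15 cases and 15
controls. The two fraction profiles were chosen once to reproduce the
qualitative scale split of real fractions — the cellular profile
(log-mean 7.0, log-sd 1.2, dispersion 0.12, negative-control mean 40) lands
its background threshold in the high tens of counts with near-complete
detection, the EV profile (log-mean 4.8, log-sd 1.6, dispersion 0.30,
negative-control mean 10) in the low tens with visibly sparser detection.
Dispersions are calibration choices reflecting typical between-subject
variability of digital counts (CV ≈ 35–55%), not inferences from any
dataset. Fold effects default to the 1.1–3× range in which real two-group
panel differences live. Outliers are multiplicative so that they survive
normalization, as real flier counts do.

What the generator does *not* emulate: batch/lane cartridge effects,
positive-control titration curves, probe-specific hybridization efficiencies,
or correlated miRNA co-expression modules. Passing the recovery and
calibration tests therefore demonstrates correctness of the pipeline's
arithmetic and reasonable statistical behaviour under a clean overdispersed
null — not performance guarantees on any particular real cohort.

## Numerical choices and degenerate inputs

* Geometric means replace zeros by 1; empty reference sets, absent negative
  controls, a single pooled negative value, groups with fewer than 2 values,
  and universes smaller than a set union are all hard errors, not silent
  defaults.
* Counts are hard integers on input; fractional counts are rejected rather
  than rounded.
* Chauvenet with a zero SD or fewer than 3 values removes nothing.
* Two constant but unequal groups cannot be t-tested (zero pooled variance)
  and fall through to the rank test; two identical constant groups report
  p = 1, direction `none`.
* Distance ties during agglomeration break on the lowest probe index; the
  leaf traversal tie-break is the cluster creation order.

## Calibration behaviour and known limitations

The test suite exercises the pipeline end-to-end on simulated null panels
(798 probes, 15 vs 15, no planted effects; single runs complete in about a
second, so the whole suite stays comfortably small). Two behaviours of the
published procedure are worth knowing:

* **The two-stage adjustment is anti-conservative.** On a heavy-tailed null
  the significant-tier fraction after the Chauvenet re-test is about
  0.06–0.08 rather than 0.05. Roughly +0.01 comes from the normality-pretest
  design itself (measured ≈ 0.057 on iid negative-binomial draws at
  n = 15/15), and a further ≈ +0.015 from selecting candidates at p < 0.1 and
  re-testing after data-dependent removal of extreme values. Users should
  treat the two-tier p values as a screening statistic, not a calibrated
  error rate — which is also why the supplementary Benjamini-Hochberg column
  is emitted.
* **Panel-wide fractions are correlated.** Shared lane and normalization
  noise correlates probes, so the run-to-run spread of the significant
  fraction exceeds the binomial standard error over probes.

Neither behaviour affects the exact bookkeeping stages (thresholds, gates,
Venn partitions), the pair-counting AUC identity, or the recovery of planted
fold-2 effects, all of which are verified against independent oracles in the
test suite.
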