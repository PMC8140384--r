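---
title: "Centroid-distance anomaly detection for registry data: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centroid-distance anomaly detection for registry data: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anomalyqc)
```

## The problem and the model

Clinical registries capture per-patient data through electronic case report
forms organized as arms → phases → forms → question groups → questions, with
answers stored as sparse attribute–value pairs (the EAV model). Data quality
suffers from carelessness, systematic error and occasional fabrication; an
automated screen that ranks patients by how atypical their records are lets
data managers spend review time where it matters.

`anomalyqc` treats every row of a flattened registry table as a feature
vector and asks how far it sits from the single global centroid (the
column-wise mean — all rows form one cluster; this is deliberately *not* a
cluster analysis). Distance is measured under up to seven metrics —
Canberra, Chebyshev, cosine, Euclidean, Manhattan, Mahalanobis, Minkowski —
because different metrics are sensitive to different deviation shapes:
Chebyshev reacts to a single extreme coordinate, Manhattan/Euclidean to
accumulated shifts, Canberra to relative change near zero, Mahalanobis to
correlation-breaking patterns. A row is anomalous under the **union rule**
(at least one active metric beyond its threshold), and the number of
exceeding metrics is the *strength of evidence* reported to data managers.

Each metric's threshold is the minimum of two bounds computed on the
distance distribution: a configurable percentile (linear-interpolation
quantile, `stats::quantile` type 7 — pinned because the IQR fence depends on
the quantile definition) and the upper Tukey fence `Q3 + 1.5·(Q3 − Q1)`.
Taking the minimum lets the percentile raise sensitivity below the fence
while the fence still catches heavy-tailed distance distributions.
"Exceeds" is strict (`>`), so a degenerate all-equal distance vector flags
nothing.

## Flattening: prefix and semi-flattened tables

Forms limited to one instance per patient are serialized into a *prefix
table* (one row per patient). Repeating forms (e.g. follow-up visits)
cannot be merged into one wide table without misaligning columns, so each
repeating form gets its own *semi-flattened table*: one row per (patient,
instance), prefix cells duplicated across a patient's rows. Detection runs
independently on each of the `n_repeating_forms + 1` tables.

Two consequences are worth knowing: anomalies spanning *different*
repeating forms cannot be seen in any single run, and a patient with no
instance of a repeating form simply contributes no row to that table
(rather than an all-missing row, which would distort imputation and the
centroid). Per-patient results are merged afterwards: maximum strength over
a patient's rows, union of flagged variables. The merge rule is this
package's choice; any monotone aggregate would be defensible, and max is
the most conservative for triage ordering.

## Preprocessing choices

The four steps run strictly in order drop → impute → recode → normalize.

* **Dropping.** Free-text variables carry notes, not analyzable signal, and
  are always dropped. A variable is also dropped when its missing fraction
  *strictly exceeds* `max_missing_fraction` (default 0.20) — exactly 20%
  missing survives.
* **Imputation.** Because imputation precedes recoding, the column median is
  undefined for labels; boolean and categorical columns therefore take the
  most frequent observed value (ties → lexicographically smallest label),
  numeric columns the median (even counts: mean of the central pair), and
  temporal columns the median of their seconds representation mapped back to
  a timestamp. Median/mode imputation pulls artificial values toward the
  centre, which *lowers* sensitivity to anomalies hidden behind missingness
  — a conservative bias.
* **Temporal recoding.** Dates, times and datetimes become seconds since
  1600-01-01T00:00:01 on the proleptic Gregorian calendar, timezone-naive.
  Because the epoch ends in `:01`, a pure date at midnight recodes to one
  second *less* than that date at 00:00:01 (so 1600-01-01 itself recodes to
  −1); we subtract epoch seconds literally rather than special-casing. The
  recode is strictly monotone in time, which is all the distances need.
* **Categorical recoding.** Unique labels get codes 0..k−1 in ascending
  frequency order (least frequent → 0), frequency ties broken by
  lexicographic label order so the recode is invariant to row order.
* **Normalization.** Min–max to [0, 1] per column. A constant column maps to
  all zeros (not dropped, not NaN): bookkeeping stays stable and it
  contributes nothing to any distance.

The recode maps, normalization ranges and drop log are all retained on the
result (and serializable to JSON) so detections can be mapped back to raw
values and a calibrated preprocessing can be re-applied.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `max_missing_fraction` | 0.20 | drop bound on per-variable missingness |
| active metrics | CAN, EUC, MAH, MAN, MINK | Chebyshev and cosine are excluded: as single-metric classifiers they perform worst (Chebyshev saturates on any one extreme coordinate in [0,1]; cosine ignores magnitude) |
| per-metric percentiles | CAN 77.5, CHEB 64, COS 95, EUC 86, MAH 88, MAN 86, MINK 83.5 | calibrated operating points; roughly, 100 − p percent of rows are inspected |
| `mink_p` | 3 | Minkowski exponent; 1 and 2 would duplicate Manhattan and Euclidean |
| `mah_ridge` | 1e-6 | diagonal regularizer before inverting the covariance; a pseudo-inverse is the fallback for residual singularity, and the route taken is recorded |
| `cell_fraction` | 0.01 | fraction of eligible cells corrupted by the simulator |
| `sigma_multiplier` | 6 | shift size for normally distributed variables |
| `rare_freq_cut` | 0.10 | observed values rarer than this form the rare-value interval |
| `shapiro_alpha` | 0.05 | normal / non-normal split for injection and post-hoc tests |
| `z_cut` | 3 | post-hoc z-score cut for normal columns |

## The anomaly simulator

Evaluation needs ground truth, so anomalies are injected into clean tables
*after* dropping/imputation/recoding but *before* normalization (injected
values must move the column's min/max the way a real out-of-range entry
would). `Nc` = `cell_fraction` × eligible cells (integer, float and
temporal columns only), rounded half-up, floor 1; `Ns` subjects are chosen
(uniform on `1..min(n_rows, Nc)` when "random" — no distribution is implied
by the design, so the least informative choice is used); each subject gets
about `Nv = Nc/Ns` corrupted variables.

Columns are split by a Shapiro–Wilk test at `shapiro_alpha`: normal columns
receive `mean ± sigma_multiplier·SD` with random sign — the "± " reading of
a 6σ shift is an interpretation, made configurable, and the injected value's
z-score against the pre-injection column is exactly 6 by construction.
Non-normal columns receive uniform draws from the closed interval spanned by
their rare values (observed frequency < `rare_freq_cut`), rounded for
integer/temporal dtypes; when nothing is rare (e.g. a constant column) the
fallback is `max + 3·IQR`, bumped strictly above the maximum when the IQR is
zero. Columns with fewer than 3 distinct values take the non-normal branch
(the test is undefined there).

Registry edit checks are modeled as an injectable predicate
`(qid, value) → accept/reject` with up to 10 redraws before a logged skip,
since real checks live inside each EDC deployment.

## Threshold calibration and ensemble selection

Per metric, an ROC curve is traced over a percentile grid (default 81
uniform points from 5 to 95; the grid is configurable) and the operating
point maximizes `C1 = norm(accuracy)² + norm(Youden)² − norm(ULC_dist)²`,
where each member is min–max normalized *across the grid candidates of that
metric's scan* (a constant member normalizes to 0 for all candidates; a
single candidate therefore scores 0). C1 ties resolve to the lowest — most
sensitive — percentile. Because the normalization reference set is the scan
itself, C1 values are comparable within a scan, not across data sets.

With thresholds fixed, every non-empty subset of the metric pool is
evaluated under the union rule and ranked by `C2 = (3·TPR + TNR)/2`
(balanced accuracy plus sensitivity — a deliberate bias toward sensitivity,
since a missed anomaly costs more than a spurious query). Ties prefer fewer
metrics, then lexicographic names. The union rule gives hard guarantees
used in the tests: a superset's sensitivity is never below, and its
specificity never above, any subset's.

Two threshold modes exist for validation on unseen data. The default
re-applies the calibrated *percentile values* to the new table's own
distance distribution — distance scales are table-specific (different
surviving columns, different ranges), so percentile choices are what
transfer across registries. Freezing the raw distance cut-offs
(`threshold_mode = "absolute"`) is appropriate only when calibration and
test tables share columns and scaling.

## What the synthetic data does and does not show

The generator emulates the *shape* of registry exports: all nine data
types, 1:N repeating forms, configurable missingness, and cohort sizes used
throughout the examples (405-patient and 29-patient profiles). Clean
matrices for simulation studies mix Gaussian and exponential columns so
both Shapiro–Wilk branches are exercised. Problem sizes in the test suite —
405×30 matrices, 20 seeds for the recovery property, 120-row calibration
tables — were chosen as the smallest sizes at which the statistical
assertions are stable.

Passing tests show the algorithm recovers *injected* anomalies of the
stated kinds (isolated 6σ shifts and rare-interval values) with high
sensitivity at the default operating points. They do not show performance
on real registries: real anomalies are not independent cell corruptions,
real columns are correlated in ways the generator only weakly mimics, and
expert-confirmed anomaly labels are absent by construction. The post-hoc
univariate tests (z-score vs Tukey-fence branch) are likewise a concrete
instantiation of an under-determined step and should be read as triage
hints, not inference.

## Numerical conventions and degenerate inputs

* Canberra 0/0 terms contribute 0; cosine distance is 1 against a zero-norm
  vector; Mahalanobis squared forms are clamped at 0 before the square root.
* Ratios with zero denominators (empty positives/negatives) are defined as
  0 in all performance measures.
* Confusion-matrix reconstruction from printed rates uses half-up rounding,
  as does the `Nc`/`Nv` arithmetic (R's banker's rounding would shift
  half-cell cases).
* Two rows are the minimum for the Mahalanobis path; one identical-rows
  table yields all-zero distances and no flags.
* Internal math runs at full precision; rounding to reporting precision
  happens only at serialization.

## Known limitations

* Cross-form anomalies (patterns spanning different repeating forms) are
  invisible to the per-table runs.
* Temporal ordering across a patient's form instances is not modeled.
* Median/mode imputation before detection can mask anomalies that manifest
  as missingness.
* The simulator's anomaly model is synthetic; sensitivity estimates
  transfer to real data only insofar as real anomalies resemble isolated
  numeric corruptions.
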