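# anomalyqc

Centroid-distance anomaly detection for clinical-registry data quality.

Clinical registries collected through electronic data capture (EDC) systems
accumulate typing errors, systematic mistakes and occasionally fabricated
values. `anomalyqc` screens registry exports for such anomalies and turns
them into actionable data-manager queries. It implements the full chain:

1. **EAV flattening** — registries store data as
   arm → phase → form → question group → question → answer. Forms that exist
   once per patient are serialized into a *prefix table* (one row per
   patient); each repeating form yields a *semi-flattened table* (one row per
   form instance, prefix columns duplicated), so every column is a single
   well-defined variable. Detection runs `n_repeating_forms + 1` times.
2. **Preprocessing** — variables with more than 20% missing data and all
   free-text variables are dropped; remaining gaps are imputed (median for
   numeric and temporal variables, mode for boolean/categorical); dates,
   times and datetimes are recoded to seconds since 1600-01-01T00:00:01;
   labels get integer codes by ascending frequency; everything is min–max
   normalized to [0, 1].
3. **Detection** — all rows form one cluster; each row's distance to the
   global centroid is measured under up to seven metrics (Canberra,
   Chebyshev, cosine, Euclidean, Manhattan, Mahalanobis, Minkowski). Each
   metric's threshold is `min(percentile threshold, Q3 + 1.5·IQR)`. A row is
   anomalous when **at least one** active metric exceeds its threshold (the
   union rule); the number of exceeding metrics is the *strength of
   evidence*. Post-hoc univariate tests (z-score for normal columns, Tukey
   fences otherwise) point at the suspect variables.
4. **Simulation & evaluation** — ground-truth anomalies are injected into
   clean tables (1% of eligible cells by default, spread over `Ns` subjects;
   normally distributed variables shifted to mean ± 6σ, others drawn from
   their rare-value interval). Thresholds are calibrated by an 81-point ROC
   percentile scan maximizing
   `C1 = norm(accuracy)² + norm(Youden)² − norm(ULC_dist)²`, and the best
   metric combination by exhaustive union-rule search maximizing
   `C2 = balanced accuracy + sensitivity = (3·TPR + TNR)/2`.

By default the active ensemble excludes Chebyshev and cosine, which perform
worst as single-metric classifiers.

## Worked example

```r
library(anomalyqc)

reg <- generate_registry(synth_config(n_patients = 30, seed = 2))
reg
#> <registry> 4 form(s) (2 repeatable), 20 question(s), 30 patient(s), 122 form instance(s)

pm <- preprocess(build_prefix_table(reg))
pm
#> <preproc_matrix> 30 row(s) x 13 column(s), normalized to [0,1]; 2 dropped variable(s)

det <- detect_anomalies(pm)   # MAH, MAN, CAN, EUC, MINK at default percentiles
det
#> <detection_result> 30 row(s), metrics {CAN, EUC, MAH, MAN, MINK}, thresholds: self; 11 anomalous

out <- run_detect(reg)        # prefix + 2 semi-flattened tables, aggregated
out$queries
#> # A tibble: 17 x 4
#>   patient_id strength flagged_variables message
#>   <chr>         <int> <list>            <chr>
#> 1 6125093           5 <chr [1]>         Patient 6125093 flagged as anomalous (s...
#> 2 8142121           5 <chr [2]>         Patient 8142121 flagged as anomalous (s...
#> ...
```

`strength` counts how many of the five active metrics flagged the patient
(5 = all of them agree); `flagged_variables` are the questions whose values
deviate univariately, i.e. what a data manager should check first. Two
variables were dropped before scoring (the free-text notes columns);
`pm$drop_log` records why.

The two-phase protocol — calibrate thresholds and the metric combination on
one registry, validate on an independent one:

```r
cal <- run_calibrate(generate_clean_matrix(405, 30, seed = 11),
                     run_config(simulation = injection_config(n_subjects = 22),
                                seed = 11))
rep <- run_validate(cal, generate_clean_matrix(29, 30, seed = 12),
                    sim_cfg = injection_config(n_subjects = 7, rng_seed = 12))
tidy(rep)   # confusion matrix + sensitivity/specificity/C2 on the unseen table
```

A thin command-line wrapper ships in `inst/cli/registry-anomaly.R`
(`synth`, `detect`, `simulate`, `calibrate`, `validate` subcommands).

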