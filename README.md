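# pswer

Detection and analysis of **paroxysmal slow-wave events (PSWEs)** in
multi-channel resting-state EEG.

EEG "slowing" — excess delta/theta power — tracks cortical involvement in
several neurological conditions, and much of it arrives as discrete,
transient episodes rather than a tonic shift. `pswer` quantifies those
episodes. The defining statistic is the **median power frequency**: for a
window with one-sided power spectrum $P(f)$, the MPF is the frequency
$f^\*$ at which

$$\sum_{f \le f^\*} P(f) \;=\; \tfrac12 \sum_{f_{\min} \le f \le f_{\max}} P(f),
\qquad (f_{\min}, f_{\max}) = (1, 45)\ \text{Hz},$$

interpolated linearly inside the crossing bin. A **PSWE** is a maximal run
of consecutive 2 s sliding windows (1 s overlap) with $\mathrm{MPF} < 6$ Hz
whose span is at least 5 s. Events are counted per subject in nine
anatomical areas (right/left/central × frontal/tempo-parietal/occipital)
obtained by unweighted spatial averaging of 10-10 electrodes, after
zero-phase FIR band-pass (1–95 Hz) and band-stop (45–55 Hz) filtering,
average re-referencing and EOG removal.

The package is aimed at clinical-neurophysiology pipelines: it reads and
writes EDF, ships the full preprocessing → regionalization → spectral →
detection → cohort-statistics chain as composable functions plus a CLI,
and includes a seeded synthetic-EEG cohort generator with planted ground
truth, so the entire chain is testable without patient data.

## Worked example

Synthesize a 4-minute, 60-channel eyes-closed recording (1/f background
plus alpha rhythm), plant one 12 s slow-wave burst at 3 Hz in the central
occipital area, and run the full pipeline:

```r
library(pswer)

spec <- synth_spec(n_channels = 60, duration_s = 240, seed = 42)
rec  <- generate_background(spec)

m   <- default_montage()
occ <- names(m$assignment)[m$assignment == 9]      # central occipital
rec <- plant_slow_event(rec, planted_event(occ, start_s = 101.5,
                        duration_s = 12, dominant_freq = 3,
                        amplitude_ratio = 5))

res <- run_subject_pipeline(rec)
res
#> <subject_result> 'synthetic': 1 event(s), 0.69% time in PSWE (240 s analyzed)
res$events
#>   subject_id area_id start_s end_s duration_s mean_mpf_hz
#> 1  synthetic       9     100   115         15    2.739316
```

The detector recovers the planted event in area 9 (the window grid
quantizes its edges: windows partially covering the burst are still
slow-dominated, so the detected span is slightly wider than the planted
101.5–113.5 s). Per-area metrics show the event rate, coverage and the
relative band-power shift it causes:

```r
res$metrics[, c("area_id", "n_events", "events_per_min",
                "pct_time_pswe", "delta", "alpha")]
#>   area_id n_events events_per_min pct_time_pswe  delta alpha
#> 1       1        0           0.00          0.00 0.0614 0.877
#> ...
#> 9       9        1           0.25          6.25 0.7572 0.188
```

Area 9 carries 0.25 events/min, spends 6.25 % of the recording in a PSWE
state, and its delta fraction jumps to 0.76 while alpha collapses — the
spectral signature of paroxysmal slowing. The 2–8 Hz threshold sweep
(`res$sweep`) shows the event appearing from 3 Hz upward with percent time
non-decreasing in the threshold.

Cohort level: `cohort_spec()` + `generate_cohort()` build a seeded cohort
whose event rate rises with a disease-duration covariate;
`group_compare()` runs per-area Kruskal–Wallis with LSD-style pairwise
follow-up and `duration_correlation()` the Spearman correlation between
duration and event counts (`merged_event_count()` collapses cross-area
co-occurrences to subject-level events).

## Command line

```sh
Rscript -e 'pswer::pswer_cli()' simulate  --config cfg.json --out cohort/
Rscript -e 'pswer::pswer_cli()' preprocess --in s1.edf --out s1_clean.edf
Rscript -e 'pswer::pswer_cli()' detect    --in s1.edf --out out/ --sweep
Rscript -e 'pswer::pswer_cli()' analyze   --in cohort/ --metadata meta.csv --out results/
```

`analyze` emits subject metrics, event, sweep and test-result tables
(CSV) plus a JSON run manifest of every parameter.

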