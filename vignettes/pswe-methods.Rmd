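---
title: "Detecting paroxysmal slow-wave events in resting-state EEG"
author: "pswer developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting paroxysmal slow-wave events in resting-state EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Diffuse "EEG slowing" — a shift of spectral power toward the delta and
theta bands — accompanies cognitive decline in several neurodegenerative
and epileptic conditions. A useful refinement of this observation is that
slowing is often not tonic but *paroxysmal*: it arrives in discrete,
transient episodes. A **paroxysmal slow-wave event (PSWE)** is defined
operationally as a stretch of time in which the **median power frequency
(MPF)** of the signal stays below a threshold (6 Hz by convention in
humans) for a minimum duration (5 s). Counting such events per minute, per
brain region, turns a vague spectral observation into an event-rate
statistic that can be compared across subjects, brain regions and
diagnostic groups, and correlated with clinical covariates such as disease
duration.

`pswer` implements this whole measurement chain for multi-channel
resting-state scalp EEG, together with a synthetic-cohort generator that
provides planted ground truth, because the clinical recordings that
motivated the method are not publicly deposited. Every stage is exercised
end-to-end against that generator in the test suite.

## The measurement model

For each subject the pipeline computes, in a fixed order:

1. **FIR filtering.** A 1–95 Hz band-pass and a 45–55 Hz band-stop
   (50 Hz mains; configurable for 60 Hz regions), both linear-phase FIRs
   designed by the Hamming-window method. The filter length follows the
   standard Hamming transition rule ($\Delta f \approx 3.3 / N$ in
   normalized frequency); the −6 dB cutoffs sit half a transition width
   outside the stated edges, so the passband holds ±0.5 dB at the edges
   and the stopband reaches ≥ 20 dB one transition width beyond them.
   Application is single-pass with the constant group delay removed —
   for symmetric taps this is exactly zero phase (event timing is never
   shifted) and leaves the magnitude response equal to the designed
   $|H(f)|$; a forward–backward pass would square the response instead.
   Edge transients are suppressed by odd-reflection padding.
2. **Channel hygiene.** Named bad channels are dropped (an input-driven
   replacement for visual inspection; ICA-style artifact correction is
   deliberately out of scope — supply externally cleaned data), every EEG
   channel is re-referenced to the instantaneous mean of all EEG channels,
   and EOG channels are removed.
3. **Spatial averaging.** The 10-10 electrodes are averaged, unweighted
   and un-normalized, into nine anatomical areas: right/left/central ×
   frontal/tempo-parietal/occipital (areas 1–9 in that order). The exact
   electrode-to-area table used by the original study is not public, so
   `default_montage()` derives the assignment from label semantics (odd
   final digit → left, even → right, trailing `z` → midline; `F`/`AF`/`Fp`
   → frontal, `C`/`T`/`P`/`CP`/`TP`/`FC` → tempo-parietal, `O`/`PO` →
   occipital). The mapping ships as an editable CSV
   (`inst/extdata/montage_1010_60.csv`) so the original table can be
   substituted; results may shift slightly under a different table.
4. **Sliding-window spectra.** 2 s windows, 1 s overlap (0.5 Hz bins at
   250 Hz), rectangular window with per-window mean removal. The window
   shape is configurable (`"hann"`); the source protocol states only
   "FFT", so rectangular is the default and is recorded in the output.
5. **MPF.** For each window, the frequency at which cumulative power over
   1–45 Hz first reaches half the band total, linearly interpolated inside
   the crossing bin; a cumulative sum that hits exactly half at a bin edge
   resolves to the lower frequency. The integration band is configurable;
   1–45 Hz is the default because the band-stop begins at 45 Hz and the
   protocol does not state a band. Windows with zero band power get an
   undefined (`NA`) MPF: they break event runs and are never silently
   dropped.
6. **Event detection.** A PSWE is a maximal run of consecutive windows
   with MPF strictly below the threshold (default 6 Hz) whose *span* is at
   least the minimum duration (default 5 s). With 2 s windows and 1 s
   stride, a run of $m$ windows spans $m + 1$ seconds — the minimal
   convention consistent with "1 s overlap" — so "5 consecutive seconds"
   means $m \ge 4$. Events truncated by the recording edge still count if
   their span reaches the minimum.
7. **Metrics.** Per area: event count, events/min, percent of analyzed
   time inside events; plus relative band powers (delta 1–5, theta 5–8,
   alpha 8–12, beta 12–20 Hz, half-open bins, normalized by the 1–45 Hz
   area under the Welch-averaged spectrum). The subject-level percent time
   is the mean of the per-area percentages (the aggregation the source
   protocol leaves unstated). A threshold sweep (2–8 Hz) re-runs detection
   at each threshold; percent time is provably non-decreasing in the
   threshold, while event counts need not be (runs merge).

Cohort statistics are deliberately nonparametric: Spearman rank
correlation (average ranks for ties, two-sided t-approximation p-values)
between event counts and a disease-duration covariate, and per-area
Kruskal–Wallis omnibus tests followed, when significant at 0.05, by
unadjusted pairwise rank-sum tests — an LSD-style policy, tagged as such
in the output. The original linear mixed model with LSD post-hoc is
off-the-shelf fitting peripheral to the event-detection method and is
intentionally not re-implemented; normal/χ² approximations are used
throughout, appropriate for cohort sizes in the tens.

## The synthetic world

`synth_spec()`/`generate_background()` emulate an eyes-closed resting
recording: 60 channels (a fixed 10-10 subset covering all nine areas),
240 s at 250 Hz, a $1/f^a$ background (default $a = 1$) synthesized in the
frequency domain with deterministic magnitudes and random phases — so the
periodogram slope is exact by construction — plus an alpha rhythm
(default 10 Hz, RMS equal to the background RMS, reflecting a prominent
eyes-closed alpha). Alpha phase is shared within an area and independent
across areas: spatial averaging then preserves the rhythm while
channel-independent background noise averages out, which keeps the
regional MPF comfortably above 6 Hz in event-free data.

`plant_slow_event()` adds a sinusoidal burst (0.5 s raised-cosine tapers;
amplitude expressed as an RMS ratio to the carrying channel) coherently on
all channels of one area, *before* spatial averaging, so the averaging
stage is genuinely exercised. `cohort_spec()` links a per-subject Poisson
event rate to a disease-duration-like covariate:
$\lambda = \max(0,\; b + s\,x)$ events/min with $x \sim U(0, 10)$ years,
defaults $b = 0.5$, $s = 0.08$ — chosen once so that a 31-subject cohort
realizes a rank correlation near 0.4 between covariate and true counts,
the regime the method targets. Event durations are drawn from 7–15 s and
dominant frequencies from 1–4 Hz with RMS ratio 5: unambiguously
detectable events, since the generator's job is ground truth for the
detector, not a hard benchmark.

What the generator does **not** model: eye-blink/EMG artifacts, electrode
drift, volume conduction or any head-model physics, and PSWE morphology
beyond a tapered sinusoid (the defining statistic is the MPF, which is
morphology-agnostic; the sinusoidal burst is an explicit assumption).
A green end-to-end test therefore establishes that the measurement chain
is correct and calibrated on its stated world — not that the pipeline is
robust to real-world artifacts.

### Average-reference leakage

One real physical effect the generator *does* reproduce deserves
emphasis. Re-referencing to the common average subtracts
$(k/60)\,A\sin(2\pi f t)$ from every channel when a coherent burst of
amplitude $A$ occupies $k$ channels; the burst therefore appears,
anti-phase and attenuated, in every *other* regional average. For a
15-channel tempo-parietal event this leaked copy is strong enough to
cross the detection threshold, so one physical event is legitimately
observed in several areas at once. Consequently:

* sensitivity is assessed per area (a planted event must be recovered in
  *its own* area), while false-positive checks match detections to planted
  events by time overlap in *any* area;
* `merged_event_count()` provides the subject-level granularity —
  detections overlapping in time are one physical event — which is the
  count used when relating event occurrence to a per-subject covariate.
  The per-area sum remains available and is the right denominator for
  per-region rate maps.

## Numerical choices and degenerate inputs

* MPF interpolation is linear inside the crossing bin; ties resolve to the
  lower frequency. A single-bin spectrum returns that bin's frequency; the
  test suite pins the implementation to an independently written
  brute-force oracle on 1000 random spectra.
* Periodogram normalization satisfies Parseval exactly (one-sided sum =
  mean square), also under the Hann taper.
* The EDF writer uses a symmetric digital range (±32767) so 0 µV is
  exactly representable; round-trips are exact to the per-channel
  quantization step (physical range / 65534). Physical extrema are
  re-parsed from their 8-character ASCII header fields before use, so the
  scale written is bit-identical to the scale read.
* All randomness is seed-derived; per-subject seeds are a deterministic
  function of the cohort seed and subject index, so any subject can be
  re-materialized in isolation (`realize_subject()`).
* Event placement rejects overlaps within an area (1000 attempts, then an
  error) and `cohort_spec()` refuses parameter combinations whose expected
  event load exceeds half the recording's area-time capacity.
* All-zero windows (undefined MPF), empty areas after exclusion (flagged
  missing, never imputed as zero), constant inputs to correlation, and
  groups smaller than two subjects all raise explicit errors or flags
  rather than propagating silent defaults.

## Scaling of the heavy validation runs

Two acceptance properties are Monte-Carlo heavy. Planted-event recovery
runs at the stated full scale (20 seeds × 60 channels × 240 s). The
end-to-end correlation-recovery property (50 cohorts × 31 subjects through
the complete pipeline) runs on 18-channel recordings — two channels per
area, 240 s, all other parameters at their defaults — to keep the suite
inside its time budget. Two channels per area is the smallest montage
that preserves the regional-averaging physics: with a single channel per
area the regional background is not averaged down at all, and the average
reference can cancel most of an area's alpha rhythm, producing spurious
near-threshold MPF dips that the full 60-channel montage does not show.

## Known limitations

* The electrode-to-area table is a reconstruction from label semantics,
  not the original appendix table.
* No artifact rejection beyond an exclusion list; recordings are assumed
  pre-cleaned.
* The EDF implementation is deliberately minimal: one shared sampling
  rate, 1 s records, no EDF+ annotations.
* Group tests are per-area with an unadjusted LSD-style follow-up — the
  permissive policy of the source protocol — so multiplicity control is
  the caller's responsibility.
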