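---
title: "Simulating and analysing P300 oddball studies on four-channel mobile EEG"
author: "oddballerp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing P300 oddball studies on four-channel mobile EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The design this package models

`oddballerp` implements the complete computational pipeline of a 2 (location:
inside, outside) x 2 (time: pre-test, post-test) fully within-subject visual
oddball experiment recorded on a four-channel consumer EEG headband (TP9,
AF7, AF8, TP10, referenced to FPz at acquisition). Each of the four sessions
per participant is an oddball task: rare target circles (30%) among frequent
standards (70%), four blocks of 100 trials, stimuli shown 800–1200 ms with a
200–500 ms fixation between trials, and no more than two targets in a row.
The measures are the P300 amplitude of the oddball-minus-control difference
wave on a pooled posterior virtual electrode, the mean reaction time to
targets, and the error count (misses plus false alarms).

Because the headband's app cannot inject event markers into the EEG stream,
markers are placed by a side channel while the samples arrive over Bluetooth
with a lag of roughly 18–20 ms (SD about 5 ms between sessions) that is
constant within a recording. The mark therefore lands on samples recorded
*before* the stimulus, and the ERP appears *later* than the mark by exactly
the lag. The simulator encodes this as
`marked_sample = nominal_sample - lag_in_samples`, with one Normal(19 ms,
5 ms) draw per recording; downstream latencies are delayed by the lag, which
is the behaviour real recordings show.

## The synthetic-data generator

`generate_study()` builds, for every participant and cell, a continuous
recording that is an exact superposition of three components:

* **1/f background noise** — Gaussian white noise shaped in the frequency
  domain to a power spectrum falling as `f^-1` (exponent configurable),
  normalised to 4 µV RMS per channel.
* **Blink artifacts** — 300 ms raised-cosine lobes of 150 µV on AF7/AF8 and
  half that on TP9/TP10, at Poisson-random times, 22 per minute.
* **Event-related templates** — a shared negative N200 Gaussian (−1 µV,
  200 ms, SD 30 ms) on every trial plus a positive P300 Gaussian (400 ms,
  SD 60 ms) on oddball trials only, full amplitude posterior and 0.3x
  frontal. The P300 amplitude of a participant's cell is the cell mean plus
  a participant offset (Normal, SD 2 µV) shared by that participant's four
  cells; individual trials jitter around it with SD 8 µV.

Cell means default to the canonical walking-study values: P300 amplitudes
1.5/1.6/1.4/2.4 µV and reaction times 220.1/218.1/221.0/213.3 ms for
inside-pre/inside-post/outside-pre/outside-post. Reaction times follow a
shifted lognormal (shift 100 ms, trial SD 85 ms, participant offset SD
25 ms, truncated at ±3 SD so no participant's mean can fall below the
shift); behavioural errors (miss or false alarm) occur at 0.003 per trial,
giving roughly one error per 400-trial session.

### How the free parameters were calibrated

The task structure, sampling rate, cell means, lag model, and the 30%
rejection target are fixed by the study design being emulated. The noise
magnitudes are not; they were set once, from the published summary
statistics, before any acceptance measurement, by inverting the standard
error arithmetic:

* The published interaction F of about 5.6 for P300 at n = 30 implies a
  per-participant interaction-contrast SD near 2.1 µV, i.e. a per-cell
  measurement SD near 1.0 µV. With ~84 retained oddball epochs per cell,
  a single-trial amplitude SD of 8 µV plus the residual of 4 µV RMS
  background noise reproduces that.
* The published RT interaction F of about 4.0 with a 5.7 ms interaction
  contrast implies a per-cell RT SD near 7.9 ms, i.e. a single-trial RT SD
  near 85 ms at ~120 hits.
* Between-participant SDs (2 µV, 25 ms) reproduce the width of the published
  between-subject cell intervals.
* A blink rate of 22/min makes the expected fraction of epochs whose window
  overlaps a blink equal the published ~30% rejection rate (simulated runs
  measure 29–31%).

These defaults are the package's definition of "a realistic session" and are
deliberately not tuned further.

### What the generator does not model

No volume conduction or realistic topography (the frontal attenuation factor
is a constant), no ocular or muscle artifact families beyond stereotyped
blinks, no alpha/beta oscillatory structure, no drift in electrode impedance,
and no within-recording marker jitter (the real system's jitter is
between-recording only, which is what the model encodes). Passing tests on
synthetic data therefore demonstrate the correctness of the *pipeline*, not
the physiological fidelity of the waveforms.

## Preprocessing

The chain mirrors standard mobile-ERP practice: a zero-phase (dual-pass)
Butterworth band-pass of 0.1–30 Hz plus a 58–62 Hz band-stop notch, 2nd
order per pass; pooling into frontal (AF7+AF8)/2 and posterior (TP9+TP10)/2
virtual electrodes; epochs from −200 to +600 ms around each *marked* onset
(51 + 1 + 154 = 206 samples at 256 Hz, onset sample on the post-stimulus
side, 0-based indices, all ms-to-sample conversions rounding half away from
zero); baseline correction by the mean of the 200 ms before onset; and
rejection of any epoch whose within-epoch range (max − min) exceeds 60 µV on
either pooled channel (strictly greater; exactly 60 µV survives).
Participants lose their data only when strictly more than half of their
epochs are rejected. The acquisition-time variance gate (each channel's
rolling 1 s variance below 200 µV²) is reported per channel offline but
never drops data silently.

Numerical choices worth stating: filtering uses odd-reflection padding of
3 s per edge before the forward and backward passes (the 0.1 Hz high-pass
has a transient of several seconds; reflection padding keeps it out of the
data), and the band-pass and notch are applied as separate cascades. The
filter core is a compiled direct-form II transposed section; it reproduces
`signal::filter` to ~1e-12. Filtering and pooling are both linear and
time-invariant, so their order is immaterial up to float tolerance; the
pipeline applies filter-then-pool and the test suite asserts the
commutation.

## Peak measurement

Per participant and cell, retained oddball and control epochs are averaged
on the posterior electrode and subtracted (oddball minus control). P300 is
the largest *local* maximum (strictly greater than both neighbours; a
plateau is represented by its first sample; ties take the earliest sample)
of the difference wave in 400–600 ms, N200 the symmetric local minimum in
150–250 ms. When a window contains no interior local extremum the window
extremum is reported and flagged `is_local_extremum = FALSE`. The windows
are fixed at those printed values rather than re-derived per run: they were
themselves chosen around grand-average peaks, and fixing them keeps the
estimator identical across simulations. Because the generator gives both
conditions the same N200, the difference-wave N200 is ~0 by construction;
the package exports N200 peaks but, as in the original analysis, runs
inferential statistics only on P300.

### A known property: local-max amplitude bias

Picking the largest local maximum of a noisy average is positively biased at
finite signal-to-noise ratio, and more so for small true amplitudes. At the
package's default noise the bias on recovered P300 cell means is roughly
+0.2 to +0.5 µV (largest for the 1.4 µV cell, smallest for 2.4 µV). This is
a property of the estimator — the same one the field uses — not of the
simulator: interaction statistics and reaction-time recoveries are
essentially unaffected, but the strict "cell means recovered unbiased within
Monte-Carlo error" acceptance check fails for P300 amplitudes and is left
failing deliberately, with this paragraph as the analysis. Mean-amplitude
measures would remove the bias but are out of scope.

## Statistics

`rm_anova_2x2()` is the classical within-subject decomposition for one
observation per participant and cell: each effect's sum of squares comes
from its marginal means, its error term from the participant-by-effect
interaction, `F = MS_effect / MS_error` on (1, n−1) df. The effect size is
partial eta squared, `SS_effect / (SS_effect + SS_error)` — the convention
for within designs (a plain eta squared cannot be recovered from printed
values that include a negative entry, so reproduction targets use F and t).
For every effect in a 2 x 2 within design, F equals the squared paired t of
the matching contrast; the suite asserts this identity on random data, and
the three-way residual is computed definitionally so the SS-sum identity is
a genuine invariant.

Interaction decomposition runs dependent-samples t tests of post vs pre
within each location (matching the published narrative), with Cohen's
`d_z = mean(d)/sd(d)` by default and the average-SD variant as an option.
All p-values are two-sided. Cell summaries carry Cousineau participant-mean
centred confidence intervals with the Morey `sqrt(c/(c-1))` correction
(c = 4 cells); because the original table does not state whether its
intervals are within- or between-subject, a plain t-interval is exported
alongside.

Degenerate inputs are defined, not accidental: identical cells give F = 0,
p = 1; zero error variance with a nonzero effect gives F = Inf, p = 0 with a
warning; the analogous rules hold for `paired_t()`.

## Reproducibility and problem sizes

One master seed is expanded into per-participant, per-cell sub-streams
(`derive_seed()`), so a dataset is bit-identical under the same
configuration and adding participants does not reshuffle existing ones.
Monte-Carlo checks use `replicate_study_config()`: n = 30 participants but
one 50-trial block per cell, with `noise_amplitude`, `trial_noise_sd` and
`rt_sd_ms` rescaled so every cell-level standard error matches the
full-length design (the equations are in that function's help page). The
test suite runs 200 such replicates for parameter recovery and power, 1,000
null simulations for type-I calibration, 10,000 sequences for the
task-design audit, and 1,000-instance brute-force oracle comparisons for
epoching, rejection, pooling, averaging and peak search. The acceptance
script runs 100 replicates plus one full-length 30-participant study.

## Limitations

The simulator's realism ends at the component inventory above; effect sizes
other than the configured means are emergent, not fitted. The statistics are
exact only for the complete 2 x 2 within design (no missing cells, df = 1
everywhere, so sphericity is moot). External deposits can be analysed only
after conversion to the package's directory layout via the documented
adapter seam (`read_external_study()`); no concrete third-party layout is
bundled.
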