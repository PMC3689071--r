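---
title: "Methods: spike-train and behavioral statistics for context-dependent fear discrimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike-train and behavioral statistics for context-dependent fear discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdfd)
```

## The experiment this package models

In context-dependent fear discrimination (CDFD), the same 30-s tone
conditioned stimulus (CS) predicts a footshock in one context (A, the
fearful context) but not in another (B, the safe context). After
discrimination training, animals are tested with CS-only trials in each
context while single units are recorded; the analysis asks whether a
unit's CS-evoked firing is gated by context. `cdfd` implements that
analysis chain — trial alignment, peristimulus time histograms (PSTH),
baseline Z-score normalization, responsive-unit classification, per-unit
context-modulation statistics, and population summaries — together with
the supporting behavioral metrics (freezing percentage and prepulse
inhibition) and a synthetic-data generator that emulates the recording
session so the whole chain is testable without recordings.

## PSTH normalization and the two resolutions

Spikes are aligned to each CS onset and counted in half-open bins
`[lo, hi)`; a spike exactly on a bin edge belongs to the upper bin, and a
spike exactly at the end of the alignment window is excluded. Two
resolutions are used, chosen so that both have exactly 20 baseline bins:

| resolution | bins | window | baseline | used for |
|---|---|---|---|---|
| fast | 50 ms | −1 to +3 s | 1 s pre-CS | short-latency responses |
| slow | 1 s | −20 to +30 s | 20 s pre-CS | sustained responses, modulation t |

The count matrix (trials × bins) is averaged across trials, and the
trial-averaged profile is expressed in SD units of its own pre-CS
baseline bins: `z[b] = (avg[b] − m) / s`, with `m` and `s` the mean and
sample SD (divisor n−1) over the 20 baseline bins of the trial-averaged
profile. The sample SD is used because the 20 baseline bins are a sample
of the unit's stationary baseline variability; nothing in the analysis
depends strongly on the n vs n−1 choice, and the more conservative
option is the default. A pooled alternative (`baseline_mode = "pooled"`,
statistics over all trials × baseline bins of the raw count matrix) is
available; it estimates single-trial variability rather than the
variability of the trial-averaged profile, so its Z values are on a
different scale and it is not the default.

If the baseline SD is zero (typically a unit that never fired during the
baseline), the Z profile is undefined. Such units are flagged
`degenerate` and excluded downstream with reason `degenerate_baseline` —
never silently dropped, and never classified.

## Responsive-unit criteria

Both criteria use a 3-SD threshold, and "over" is strict (a bin at
exactly 3 SD does not qualify):

* **Short-latency CS-responsive** — at least one of the first three
  post-CS 50-ms bins (the 0–150 ms window) has `z > 3`.
* **Persistently firing unit (PFU)** — two or more of the first ten
  post-CS 1-s bins (0–10 s) have `z > 3`.

Units are classified once, on trials pooled across both contexts, and
the contexts are compared afterwards; classifying per context (a unit is
responsive if it qualifies in either context) is available via
`classify_contexts = "per_context"`. Raising the threshold is monotone:
the responsive set at 4 SD is a subset of the set at 3 SD, which the
test suite checks by property.

## The context-modulation t-value

For each unit, the CS response is summarized per context at the slow
resolution and contrasted over the thirty matched 1-s CS bins:
`d[b] = zA[b] − zB[b]`, and

```
t = mean(d) / (sd(d) / sqrt(30)),   df = 29
```

with two-tailed significance at α = 0.05 (critical |t| ≈ 2.045). A
positive t-value means more CS-evoked activity in the fearful context A.
The raw sum of differences is reported alongside for transparency. If
`sd(d) = 0` with a nonzero mean the statistic is undefined; the result
is flagged degenerate with its direction preserved.

### Why the contrast uses a common baseline

A subtle calibration issue drives one deliberate design choice. If each
context's profile is normalized to its *own* 20-bin baseline, the error
in each baseline-mean estimate is constant across the 30 matched bins:
it shifts `mean(d)` but contributes nothing to `sd(d)`. The t statistic
then has an inflated null distribution — the inflation factor is about
`sqrt(1 + 30/20) ≈ 1.58`, which empirically turns the nominal 2.5%
per-direction false-positive rate into roughly 10%. Normalizing *both*
contexts' profiles to a common baseline (mean and SD of the pre-CS bins
pooled over all trials of both contexts) makes the baseline-estimation
error common mode, so it cancels exactly in `d`, and the scale factor
cancels inside t; the statistic then sits at its nominal t(29) null
level. This common baseline is the default (`context_baseline =
"common"`) and is also used for the paired window tests and population
profiles. The per-context variant remains available
(`context_baseline = "per_context"`); it additionally removes any
context difference in spontaneous rate from the contrast, at the cost of
the inflated null level above, so its t-values should be read as
descriptive rather than calibrated.

## Population-level statistics

* **Direction chi-square.** Among the PFUs, the proportion of
  significantly positive t-values is compared with the proportion of
  significantly negative ones via a Pearson chi-square (no continuity
  correction, df = 1) on the 2×2 table
  `[[n_pos, n − n_pos], [n_neg, n − n_neg]]`. With 11 positive and 3
  negative of 24 units this construction gives χ² = 6.454. The
  population it is computed over is configurable
  (`chisq_population = "persistent"` by default, `"analyzed"` for all
  units with a defined t-value).
* **Paired window tests.** Per-unit window means (0–150 ms across
  short-latency units; 0–10 s and the whole CS across PFUs) are paired
  across contexts and tested with a paired t (df = units − 1).
* **Population profiles.** Bin-wise mean ± SE of the per-unit Z profiles
  per context.
* **Habituation split.** Each context's 6 trials are divided into an
  early (1–3) and late (4–6) phase; Z-scores are recomputed within each
  context × phase cell against that phase's own baseline bins, averaged
  over the response window, and analyzed with a two-within-factor
  repeated-measures ANOVA (context, phase, context × phase; unit as the
  random factor; each effect tested against its own subject-interaction
  error term). In the short-latency variant, units that did not fire
  during the 1-s pre-CS baseline throughout the early or late trials are
  excluded. A mixed between/within decomposition (`mixed_anova`) is
  provided as oracle-tested plumbing for group × context behavioral
  designs.

Both ANOVA decompositions are checked against `stats::aov` with the
matching `Error()` strata to 1e-10 in the test suite; `aov` is used only
as an independent oracle there, never as the implementation.

## Behavioral metrics

Freezing — immobility except for respiration — arrives as annotated
intervals. The freezing percentage over an analysis window (the first CS
presentation per context in the discrimination test) is the measure of
the union of the intervals intersected with the window, divided by the
window length; overlapping or touching intervals merge, so the metric is
invariant to how an annotation is split. Prepulse inhibition is the
printed formula `PPI (%) = 100 × (SS − PS) / SS` on mean startle
amplitudes, defined only for `SS > 0` and invariant to amplitude
rescaling.

## The synthetic-data generator

The generator emulates the test-session structure: per context, a 180-s
pre-tone exposure followed by 6 CS-only trials (30-s tone) with
inter-trial intervals drawn uniformly from 160–200 s (mean 180 s); the
two context sessions are laid end to end on one time base so unit
identities match across contexts, as the paired statistics require.

Each unit is an inhomogeneous Poisson process realized by Lewis–Shedler
thinning. Its rate is a baseline (spikes/s) modulated around CS onset by
two context-gated components:

* a **transient** gain over the first 150 ms, and
* a **sustained** gain at onset decaying linearly to 1 at 10 s — the
  simplest shape that confines differential firing to the first ~10 s of
  the tone.

The components combine multiplicatively by default (`combine =
"additive"` is available). Cohort baseline rates are drawn log-uniformly
over 0.31–34.6 Hz, the spontaneous-rate range of the recorded population
the generator emulates. Simultaneous timestamps are perturbed by one
timestamp-resolution unit (1e-4 s) so trains are strictly increasing.
Freezing annotations are generated by freezing each 1-s segment of a CS
window independently with the context's probability, making the expected
freezing percentage exactly 100 × probability; startle amplitudes are
log-normal with the prepulse-startle mean scaled to the requested true
PPI.

What the generator does *not* emulate: refractoriness, bursting and
spike-sorting artifacts; non-stationary baselines (drift, state
changes); US-evoked responses and lesion effects; correlations between
units; and video-scored freezing (annotations are taken as given).
Passing tests therefore demonstrate that the statistics behave correctly
for Poisson-like units under the stated trial structure, not that the
biological assumptions hold in any particular recording.

## Problem sizes and conditions used in the checks

The packaged checks use cohort sizes chosen to balance Monte-Carlo
resolution against desk-scale runtimes, stated here as the package's own
choices:

* generator calibration: homogeneous 5 Hz over 180 s, 100 seeds (3-SE
  bound on the mean count of 900);
* null calibration: 500 units with equal gains in both contexts; the
  significantly-positive and -negative rates are required to fall in
  [1%, 4%] around the nominal 2.5%;
* parameter recovery: 50 seeds × 24 units, half with context-A transient
  gain 4 and sustained gain 2. Baseline rates for this cohort are drawn
  log-uniformly over 2–20 Hz — representative of the CS-responsive
  population on which per-unit t-values are computed (reported mean
  spontaneous rates near 6–8 Hz) rather than of the full population,
  whose lowest-rate units carry too few spikes for any per-unit
  statistic;
* criterion equivalence: 1,000 random count matrices against a
  brute-force evaluation of the printed criteria; the chi-square is
  checked exhaustively over all 2×2 tables with margins ≤ 30.

## Numerical choices and degenerate inputs

* Bin assignment rounds the time/width ratio at 1e-9 before flooring, so
  boundary spikes land deterministically in the upper bin regardless of
  floating-point representation; windows must be integer multiples of
  the bin width (checked at 1e-9).
* Strict inequalities at the 3-SD threshold; ties are non-responsive.
* Zero-variance cases are always flagged, never coerced: degenerate
  baselines exclude a unit with a recorded reason; zero-variance
  difference vectors flag the t-value as undefined (direction kept).
* `n_total = n_analyzed + n_excluded` holds for every report, and
  summary counts equal the per-unit table tallies.
* Reports are deterministic given inputs and seeds; generation under one
  seed is byte-identical across runs, and the RNG state of the caller is
  restored.

## Known limitations

The per-unit t over 30 bins treats bins as exchangeable pairs; when a
response is concentrated in a few bins, between-bin signal heterogeneity
inflates `sd(d)` and bounds the attainable t, so the statistic is
conservative for sharply transient modulation. The chi-square
construction compares two overlapping proportions from the same units
and is reported as the field's convention rather than as an optimal
test. Low-rate units (below roughly 1 Hz) yield discrete, noisy Z
profiles; they are retained unless degenerate, but their per-unit
statistics carry little power.
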