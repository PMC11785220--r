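---
title: "Actigraphy sleep and light analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Actigraphy sleep and light analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somna)
```

`somna` implements the full analysis chain of a field actigraphy study of
sleep across living environments and seasons: epoch-level sleep/wake
scoring, nightly rest-interval detection, diary-based quality control,
circular clock-time statistics, the Sleep Regularity Index (SRI), 24-h
activity waveforms, 50-lux light-exposure metrics, and the group
statistics layer. This vignette records the models, their assumptions,
and the choices made where the design was genuinely open.

## Time representation

Clock times are minutes after midnight in `[0, 1440)`. Sleep-timing
parameters cross midnight, so nightly onset/offset are carried
noon-referenced (minutes after the preceding 12:00), which makes a night
a contiguous interval and lets the linear-model layer analyse timing on
an ordinary linear scale without wrap artifacts. Light-exposure times are
morning/evening events within a civil day and stay midnight-referenced.
Participant-level means and intraindividual SDs of clock times use
directional statistics: the mean is the direction of the summed unit
vectors at angle `2*pi*minutes/1440`, the SD is
`sqrt(-2 log R) * 1440 / (2*pi)` minutes with `R` the mean resultant
length. On a concentrated arc these agree with linear statistics to
within a few minutes (a property the tests assert); near-uniform or
antipodal configurations have no mean direction and raise an error
rather than returning an arbitrary value. Linear SDs on the
noon-referenced scale are emitted alongside (`sd_*_linear`) as
diagnostics, since published reports rarely state which estimator was
used.

Epoch timestamps are treated as local civil time with no daylight-saving
adjustment inside a recording; recordings are a few weeks long, and the
analyses depend only on clock structure, not on UTC offsets.

## Sleep scoring

The scorer is an open member of the published weighted-window family for
wrist actigraphy. Epoch *t* (60-s grid) is scored sleep iff

`W_t = A_t + 0.2 (A_{t-1} + A_{t+1}) + 0.04 (A_{t-2} + A_{t+2}) <= 40`,

with missing neighbours contributing zero and off-wrist epochs scoring
missing. All constants live in `scoring_params()`: the neighbour weights
(0.2, 0.04), the threshold (40 counts — the conventional medium
sensitivity), the onset/offset anchor run (10 consecutive immobile
minutes), and the rest-interval detector settings. 15-s recordings must
first be brought to the 60-s grid with `resample_epochs()` (counts are
extensive and sum; lux averages; a trailing partial window is dropped
rather than scaled, to avoid inventing counts).

The main nightly rest interval is the longest span inside an
18:00–12:00 search window whose 10-min running-mean activity stays at or
below half the median smoothed activity of the whole recording, subject
to a 160-min minimum, with ties broken toward the earlier span. Three
deliberate details:

* **Recording-wide median reference.** A day-local median collapses on
  nights when sleep fills most of the surrounding noon-to-noon day (long
  sleepers), silently truncating the interval; the recording-wide median
  stays anchored at waking activity. Activity levels are assumed roughly
  stationary across a recording, which holds for wrist counts at these
  time scales.
* **Bridging brief interruptions** (`max_interrupt`, 20 min): a single
  restless stretch can push one smoothed window over threshold and would
  otherwise split the night into two spans, assigning the night a
  half-length interval. Commercial rest-interval detectors are similarly
  tolerant.
* **Edge padding.** The smoothed detector blurs interval edges by about
  half a smoothing window, so the onset/offset run search extends
  `smooth_minutes` beyond the interval on each side. Onset is the start
  of the first run of 10 consecutive sleep-scored epochs, offset the end
  of the last; duration, midsleep and in-sleep activity follow. With the
  default generator's waking activity (~250 counts/min), the weighted
  window introduces at most a one-epoch latency at each edge.

A night in which no qualifying run exists is a *sleepless candidate*; it
becomes a sleepless night only if the diary also has no entry for that
date. A candidate with a diary entry present is excluded as missing data
rather than imputed from the diary — the watch and the participant
disagree, and the package flags rather than guesses.

## Quality control

Three filters, all idempotent and commuting on the surviving set:

* nights whose watch-determined onset or offset differs from the
  diary-reported bedtime/waketime by more than 3 h — as a circular
  difference, so 23:50 vs 00:10 is 20 min, not 23 h 40 min — are
  excluded (strict inequality: exactly 3 h is kept);
* nights slept away from the participant's usual site (diary location
  classified per community through a configurable map; unmapped strings
  are kept and reported, missing locations kept);
* participants with fewer than 14 surviving nights, and overnight-shift
  workers, are dropped. Sleepless nights are observed nights and count
  toward the minimum — they are data, not missingness.

## Sleep Regularity Index

`SRI = -100 + (200/P) * sum over valid pairs of 1[same state]`, where a
valid pair is the same minute-of-day on consecutive days with both
states observed, and `P` is the number of valid pairs. An unbroken
routine scores 100; day-to-day independence scores ~0. Consecutive-day
pairs (not all day pairs) implement the "24 hours apart" definition.
Missing epochs — off-wrist gaps and QC-excluded nights, which are masked
noon-to-noon — are dropped from `P` rather than imputed, which is
unbiased under missing-at-random. The implementation is tested against a
brute-force pair-counting oracle and its closed forms (+100, 0, -100).

## Waveforms and light exposure

Waveforms: per day, raw 1-min counts are averaged into 48 half-hour
bins, transformed by `log10(x + 1)` (the pseudocount keeps zero-activity
bins finite; the base is cosmetic), smoothed by a 3-bin (1-h) running
mean that wraps across midnight (the day is circular, and the 07:00
morning window sits close to the midnight seam), and averaged across
days. Wrapped smoothing is mean-preserving per day. Morning/evening
window totals sum raw counts inside season-specific windows (summer
07:00–10:00 and 19:00–21:30; winter 07:00–09:00 and 20:00–22:00) and are
divided by days recorded, so participants with different recording
lengths are comparable.

Light: for each civil day, the first and last epoch at or above the lux
threshold (inclusive; default 50 lux, a conventional level above the
likely threshold for circadian photic stimulation) and the total minutes
above it. Days are bounded at civil midnight because first/last exposure
are diurnal events. Start-of-epoch times are reported; at 1-min
granularity the distinction from end-of-epoch is immaterial.
Participant summaries average first/last times circularly over days with
any exposure; zero-exposure days contribute 0 to mean duration but are
omitted from timing means.

## Group statistics

* Per season, each sleep parameter (participant-level mean onset,
  offset, midsleep on the noon-referenced scale, and duration) is fitted
  by least squares with community (housed reference) and gender as
  factors; community coefficients estimate adjusted differences from
  housed, and gender gets a type-II F-test.
* SRI, in-sleep activity, and the intraindividual SDs are compared by
  one-way ANOVA with Dunnett many-to-one contrasts against housed
  (single-step multivariate-t adjustment, via `multcomp`); with two
  groups this reduces exactly to the pooled t-test.
* Variance homogeneity across communities uses Bartlett's chi-squared.
* Sleepless vs. slept night counts across communities use Pearson's
  chi-squared without continuity correction (the table is larger than
  2x2); an expected cell below 1 attaches a warning.
* Daily light metrics are fitted by a linear mixed model
  `value ~ community * season + gender + (1 | participant)` (via
  `lme4`/`lmerTest`, Satterthwaite F-tests) with Tukey-adjusted all-pairs
  comparisons among community-by-season cells (via `emmeans`). The
  participant-level random intercept reflects that the repeated unit is
  the participant-day. Ordered residual quantiles are returned for QQ
  normality checks. With one observation per participant the fit
  degenerates to ordinary least squares, a reduction the tests assert.
* Waveforms are compared by a two-way mixed ANOVA with community between
  participants and time bin within (`aov` with an `Error(participant)`
  stratum), tested against an explicit sums-of-squares oracle and a null
  uniformity check of the interaction p-value.

Monte-Carlo size checks (1000 null replicates) hold the Dunnett
family-wise and Bartlett type-I error at 0.05 ± 0.02.

## The synthetic cohort

The generator exists because raw cohort recordings of this kind are not
publicly shareable; every downstream stage is therefore validated by
parameter recovery against the generator's ground truth. Each
community-by-season profile specifies: mean onset/offset (anchored to
field-typical values, e.g. winter housed 8 h 24 min vs. 6 h 50 min –
7 h 09 min in sheltered communities); between-person SD (a person-level
effect shared by onset and offset) and within-person SD, the latter
scaled by `1 - schedule_rigidity` so the rigid overnight-shelter
schedule (doors ~21:00, departure before 08:00) has little
night-to-night jitter; per-night sleepless and off-site probabilities
(a few percent, highest in tent and tiny-house communities);
environment light transmission (tent ~0.9 down to ~0.03 for indoor
communities, winter values halved for overcast attenuation) applied to a
clear-sky solar profile at 47.6°N, plus evening indoor lux while awake;
and the activity-count model.

Counts are gamma distributed (right-skewed): waking epochs at ~250
counts/min (with a two-peak morning/evening modulation for
rigid-schedule shelters), sleeping epochs at the profile's in-bout mean
(10–29 counts/min across communities). Within a sleep bout, the first
and last 20 min are near-immobile (settling in and final waking, mean 3
counts/min) and the interior mean is raised to preserve the configured
bout mean. This temporal structure is an explicit modelling assumption,
not a claim about any specific device: independent counts at the bout
mean would park restless sleepers' weighted scores at the wake threshold
and fragment the scored bout in a way real wrist data do not show, while
the chosen structure yields onset/offset recovery within ~1 min (median)
and preserves the configured in-bout activity. Sleepless nights carry
waking-level activity all night and never produce a diary entry,
matching the sleepless-night definition. Diary times are truth plus
t(3)-distributed error (scale 10 min), missing at 15%; off-wrist gaps of
30–120 min occur on ~2% of days. The solar model is
`120000 * max(0, sin(solar elevation))` lux from standard
solar-declination geometry; at 47.6°N (Seattle's latitude) the
solstice daylength difference is 7.6 h. No weather, naps, or spectral
channels are modelled.

Per-participant seeds derive from the master seed by a counter scheme
over sorted profile names, so cohorts are reproducible and invariant to
config insertion order. The 15-s summer overnight-shelter arm is
generated by multinomial thinning of 60-s counts, conserving totals.

What passing recovery tests show — and do not show: they demonstrate
that the pipeline's estimators are consistent with their own data model
(timing recovered within ±15 min at cohort scale, exactly at zero
noise; sleepless fractions within binomial bounds; seasonal light
contrasts ordered correctly). They do not validate the scorer against
polysomnography or device-proprietary algorithms, and real data bring
nonstationary routines, naps scored as rest, and device artifacts the
generator does not emulate.

## Problem sizes and numerical choices

The acceptance workflow simulates a study-scale cohort (98 participants,
2–7 weeks each at 1-min epochs) and completes in about a minute; the
test suite uses smaller cohorts (typically 2–8 participants, 14–28
nights) chosen so each property is exercised at meaningful power.
Degenerate inputs are errors, not silent defaults: empty time sets and
antipodal circular means, single-day SRI matrices, zero within-group
variance in Bartlett's test, all-zero contingency rows, polar latitudes.
Ties in rest-interval detection break toward the earlier span;
`which.max` semantics make that deterministic. Clock values within
1e-6 min of 24:00 snap to 0 to avoid a floating-point wrap.
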