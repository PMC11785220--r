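# somna

Wrist actigraphy is the standard objective field measure of sleep where
polysomnography is impractical — including studies of sleep disparities
across housing conditions, where self-report instruments lack the
resolution to detect differences in sleep timing and quality between,
say, a tiny-house village and a congregate overnight shelter. `somna` is
an R package plus a numbered analysis workflow that takes epoch-level
actigraphy (activity counts and white-light lux), daily sleep diaries and
a participant roster through the complete analysis chain used in such
studies:

1. **Sleep scoring.** An open weighted-window scorer: epoch *t* is sleep iff

   `W_t = A_t + 0.2 (A_{t-1} + A_{t+1}) + 0.04 (A_{t-2} + A_{t+2}) <= 40`

   with the nightly rest interval found as the longest smoothed
   low-activity span in an 18:00–12:00 search window and onset/offset
   anchored by runs of 10 consecutive immobile minutes.
2. **Quality control.** Nights with more than a 3-h circular discrepancy
   between watch and diary timing, and nights slept off the usual site, are
   excluded; a night with no detected sleep and no diary entry is a
   *sleepless night*; participants need 14 surviving nights.
3. **Sleep metrics.** Per participant: circular means and circular SDs of
   onset, offset and midsleep; mean duration over slept nights; the Sleep
   Regularity Index
   `SRI = -100 + (200/P) * sum over valid pairs 1[state equal]`
   over same-clock-minute state pairs on consecutive days; mean activity
   counts/min within the scored sleep bout.
4. **Waveforms and light.** 48-bin smoothed log10 activity waveforms,
   season-specific morning/evening window totals, and daily first/last
   times and duration of exposure at or above 50 lux.
5. **Group statistics.** Per-season linear models of each sleep parameter
   against the housed reference (gender-adjusted), one-way ANOVA with
   Dunnett many-to-one contrasts, Bartlett variance-homogeneity tests,
   chi-squared on sleepless-night counts, linear mixed models of the daily
   light metrics with Tukey all-pairs post-hocs, and a two-way mixed ANOVA
   (community x time-of-day) on the waveforms.

Because raw recordings from such cohorts are generally not shareable, the
package includes a seeded synthetic-cohort generator
(`generate_cohort()`) with community/season sleep-schedule profiles,
photoperiod-driven lux at Seattle's latitude (47.6°N) with
environment-specific light transmission, right-skewed activity counts,
sleepless nights, and noisy/missing diaries — so the entire pipeline is
testable by parameter recovery against known ground truth.

## Worked example

```r
library(somna)

cc  <- cohort_config(c(housed.winter = 4, tent.winter = 4), n_days = 16)
cfg <- pipeline_config("simulate", cohort_config = cc, seed = 7)
res <- run_pipeline(cfg)

d <- merge(res$participant_summary, res$roster, by = "participant_id")
aggregate(cbind(mean_duration, sri) ~ community, data = d, FUN = mean)
#>   community mean_duration      sri
#> 1    housed      504.5781 76.71875
#> 2      tent      482.3349 56.67420
```

Housed winter participants here sleep ~8 h 25 min on average with a Sleep
Regularity Index near 77; tent dwellers sleep almost as long but far less
regularly (SRI ~57) — regularity, not duration, separates the groups.
`res$stats_results` holds the full comparison table (linear-model
coefficients vs. housed, Dunnett contrasts, Bartlett tests, the light
mixed models), and `res$nights`, `res$light_days`, `res$waveforms` the
underlying tables.

The `analysis/` directory runs the same chain at study scale as five
numbered scripts (simulate → score/QC → sleep metrics → waveforms/light →
group statistics), writing all result tables under `results/` and the
large intermediate epoch files under `scratch/`:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_score_and_qc.R
Rscript analysis/03_sleep_metrics.R
Rscript analysis/04_waveforms_light.R
Rscript analysis/05_group_stats.R
```

## Vignette

`vignettes/methods.Rmd` documents the scoring algorithm and its
parameters, the circular statistics, the SRI definition, the
synthetic-cohort model and what it does and does not emulate, and the
numerical design choices.
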