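#!/usr/bin/env Rscript

# Stage 5 — the group-comparison layer.
#
# Per season: linear models of each sleep parameter against the housed
# reference (gender-adjusted), ANOVA + Dunnett many-to-one tests for SRI,
# in-sleep activity and intraindividual SDs, Bartlett variance tests, and
# window-total ANOVAs plus the waveform two-way mixed ANOVA. Across
# seasons: chi-squared on sleepless nights and linear mixed models of the
# daily light metrics with Tukey all-pairs post-hocs. Writes
# stats_results.csv and prints the headline comparisons.

suppressPackageStartupMessages(library(somna))

summaries <- read.csv("results/participant_summary.csv")
light_sum <- read.csv("results/light_summary.csv")
names(light_sum)[names(light_sum) == "mean_first_time"] <- "mean_first_light"
names(light_sum)[names(light_sum) == "mean_last_time"] <- "mean_last_light"
names(light_sum)[names(light_sum) == "mean_duration"] <- "mean_light_duration"
summaries <- merge(summaries, light_sum[, c("participant_id", "mean_first_light",
                                            "mean_last_light",
                                            "mean_light_duration")],
                   by = "participant_id")
nights <- read.csv("results/nights.csv")
light_days <- read.csv("results/light_days.csv")
window_totals <- read.csv("results/window_totals.csv")
roster <- read.csv("results/roster_included.csv")
wf_long <- read.csv("results/waveforms.csv")
waveforms <- lapply(split(wf_long, wf_long$participant_id), function(x)
  x$value[order(x$bin_start_min)])

stats_tab <- pipeline_group_stats(summaries, nights, light_days,
                                  window_totals, waveforms, roster)
write.csv(stats_tab, "results/stats_results.csv", row.names = FALSE)
cat(sprintf("wrote results/stats_results.csv (%d rows)\n\n", nrow(stats_tab)))

show <- function(tab, msg) {
  cat(msg, "\n")
  print(tab[, c("label", "estimate", "statistic", "p_value")], digits = 3,
        row.names = FALSE)
  cat("\n")
}
lmw <- stats_tab[stats_tab$test == "lm" & stats_tab$season == "winter" &
                   stats_tab$outcome == "mean_duration", ]
show(lmw, "winter sleep duration vs housed (linear model, minutes):")
sriw <- stats_tab[stats_tab$test == "anova_dunnett" &
                    stats_tab$season == "winter" & stats_tab$outcome == "sri", ]
show(sriw, "winter SRI: ANOVA omnibus and Dunnett contrasts vs housed:")
chi <- stats_tab[stats_tab$test == "chi_squared", ]
show(chi, "sleepless nights by community (chi-squared):")
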