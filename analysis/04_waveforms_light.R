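#!/usr/bin/env Rscript

# Stage 4 — 24-h activity waveforms and 50-lux light exposure.
#
# Builds each participant's smoothed log-activity waveform (48 half-hour
# bins), season-specific morning/evening window totals, and daily 50-lux
# light metrics (first/last exposure time, daily duration). Writes
# waveforms.csv, window_totals.csv, light_days.csv and appends light
# summaries to the participant summary.

suppressPackageStartupMessages(library(somna))

roster <- read.csv("results/roster_included.csv")
in_dir <- "scratch/cohort"

wf <- list(); wt <- list(); ld <- list(); ls <- list()
for (i in seq_len(nrow(roster))) {
  pid <- roster$participant_id[i]
  s <- read_epoch_csv(file.path(in_dir, sprintf("epochs_%s.csv", pid)))
  if (s$epoch_length != 60) s <- resample_epochs(s, 60)
  w <- participant_waveform(s)
  wf[[pid]] <- data.frame(participant_id = pid,
                          bin_start_min = (seq_along(w) - 1) * 30, value = w)
  win <- season_windows(roster$season[i])
  wt[[pid]] <- data.frame(participant_id = pid,
                          morning = window_activity_totals(s, win$morning),
                          evening = window_activity_totals(s, win$evening))
  days <- daily_light_metrics(s, threshold = 50)
  days$participant_id <- pid
  ld[[pid]] <- days
  ps <- participant_light_summary(days)
  ps$participant_id <- pid
  ls[[pid]] <- ps
}

write.csv(do.call(rbind, wf), "results/waveforms.csv", row.names = FALSE)
write.csv(do.call(rbind, wt), "results/window_totals.csv", row.names = FALSE)
write.csv(do.call(rbind, ld), "results/light_days.csv", row.names = FALSE)
write.csv(do.call(rbind, ls), "results/light_summary.csv", row.names = FALSE)

d <- merge(do.call(rbind, ls), roster, by = "participant_id")
agg <- aggregate(mean_duration ~ community + season, data = d, FUN = mean)
names(agg)[3] <- "mean_50lux_duration_min"
cat("mean daily minutes at or above 50 lux:\n")
print(agg, digits = 4)
cat("wrote results/waveforms.csv, window_totals.csv, light_days.csv, light_summary.csv\n")
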