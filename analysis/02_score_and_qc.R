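#!/usr/bin/env Rscript

# Stage 2 — sleep scoring and quality control.
#
# Reads the cohort written by 01_simulate_cohort.R, scores every epoch
# sleep/wake with the weighted-window algorithm, detects each night's main
# rest interval, resolves sleepless candidates against the diary, and
# applies the inclusion rules (3-h diary discrepancy, off-site nights,
# 14-night participant minimum). Writes nights.csv and exclusions.csv.

suppressPackageStartupMessages(library(somna))

in_dir <- "scratch/cohort"
roster <- read_roster_csv(file.path(in_dir, "roster.csv"))
diary <- read_diary_csv(file.path(in_dir, "diary.csv"))
files <- list.files(in_dir, pattern = "^epochs_", full.names = TRUE)
series <- lapply(files, read_epoch_csv)

params <- scoring_params()
nights <- do.call(rbind, lapply(series, function(s) {
  if (s$epoch_length != 60) s <- resample_epochs(s, 60)
  score_nights(s, params)
}))
nights <- flag_sleepless_nights(nights, diary)
cat(sprintf("scored %d nights for %d participants; %d sleepless\n",
            nrow(nights), length(series), sum(nights$sleepless, na.rm = TRUE)))

qc <- qc_nights(nights, diary, roster)
cat(sprintf("night exclusions: %d diary discrepancy, %d off-site, %d missing data\n",
            sum(qc$nights$exclusion_reason == "diary_discrepancy"),
            sum(qc$nights$exclusion_reason == "offsite"),
            sum(qc$nights$exclusion_reason == "missing_data")))
dropped <- qc$report$excluded_participants
cat(sprintf("participants dropped: %d (%s)\n", nrow(dropped),
            paste(unique(dropped$reason), collapse = ", ")))

write.csv(qc$nights, "results/nights.csv", row.names = FALSE)
write.csv(qc$report$night_counts, "results/exclusions.csv", row.names = FALSE)
write.csv(qc$roster, "results/roster_included.csv", row.names = FALSE)
cat("wrote results/nights.csv, results/exclusions.csv, results/roster_included.csv\n")
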