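#!/usr/bin/env Rscript

# Stage 3 — per-participant sleep metrics.
#
# Aggregates QC-filtered nights into one row per participant: circular
# means/SDs of onset, offset and midsleep, arithmetic duration statistics
# (sleepless nights counted but never averaged into duration), the Sleep
# Regularity Index from the epoch-level state matrix, and mean in-sleep
# activity. Writes participant_summary.csv.

suppressPackageStartupMessages(library(somna))

nights <- read.csv("results/nights.csv")
nights$night_date <- as.Date(nights$night_date)
roster <- read.csv("results/roster_included.csv")
in_dir <- "scratch/cohort"

summaries <- lapply(roster$participant_id, function(pid) {
  s <- read_epoch_csv(file.path(in_dir, sprintf("epochs_%s.csv", pid)))
  if (s$epoch_length != 60) s <- resample_epochs(s, 60)
  pn <- nights[nights$participant_id == pid, ]
  sm <- state_matrix(s, mask_nights = pn$night_date[pn$excluded])
  sri <- tryCatch(sleep_regularity_index(sm), error = function(e) NA_real_)
  participant_sleep_summary(pn, sri = sri)
})
summaries <- do.call(rbind, summaries)

write.csv(summaries, "results/participant_summary.csv", row.names = FALSE)

d <- merge(summaries, roster, by = "participant_id")
agg <- aggregate(cbind(mean_duration, sri, mean_in_sleep_activity) ~
                   community + season, data = d, FUN = mean)
agg$duration_hm <- format_clock(agg$mean_duration)
cat("community means (duration as H:MM):\n")
print(agg, digits = 3)
cat("wrote results/participant_summary.csv\n")
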