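#!/usr/bin/env Rscript

# Stage 1 — simulate the synthetic actigraphy cohort.
#
# Generates a two-season, five-community cohort (housed controls plus
# continuous-occupancy shelter, overnight shelter, tiny-house and tent
# communities) with the study-scale sample sizes and recording lengths, and
# writes the standard CSVs (roster, diary, per-participant epoch files, and
# the generator's ground truth) under scratch/cohort/.

suppressPackageStartupMessages(library(somna))

seed <- 1234
out_dir <- "scratch/cohort"

cc <- default_cohort_config()
cat("communities and seasons:\n")
print(data.frame(group = names(cc$counts), participants = as.integer(cc$counts),
                 nights = as.integer(cc$n_days[names(cc$counts)]),
                 row.names = NULL))

cohort <- generate_cohort(cc, seed = seed)
paths <- write_cohort(cohort, out_dir)

cat(sprintf("\nwrote %d participants, %d diary rows, %d truth rows to %s\n",
            nrow(cohort$roster), nrow(cohort$diary), nrow(cohort$truth),
            out_dir))
cat(sprintf("sleepless nights in truth: %d (%.1f%%)\n",
            sum(cohort$truth$sleepless),
            100 * mean(cohort$truth$sleepless)))
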