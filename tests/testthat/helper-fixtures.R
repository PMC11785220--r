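# Shared fixtures: all synthetic, built in code at test time.

# A multi-night square-wave recording: zero activity (sleep) between
# `sleep_start` and `sleep_end`, constant `wake` counts otherwise.
# wake = 150 keeps the weighted score of edge sleep epochs at
# 0.24 * 150 = 36 <= 40, so scored onset/offset land exactly on the edges.
square_series <- function(n_days = 3, sleep_start = "23:00",
                          sleep_end = "07:00", wake = 150, lux = 0,
                          start_date = "2023-01-09", id = "sq") {
  on <- parse_clock(sleep_start); off <- parse_clock(sleep_end)
  n <- (n_days + 1) * 1440
  mod <- (seq_len(n) - 1) %% 1440
  asleep <- if (on > off) (mod >= on | mod < off) else (mod >= on & mod < off)
  # first partial and last partial nights are genuine sleep too
  act <- ifelse(asleep, 0, wake)
  epoch_series(id, paste(start_date, "00:00:00"), 60, act,
               rep(lux, n))
}

# Zero-noise community profile: deterministic counts, no timing variance.
zero_noise_profile <- function(community = "housed", season = "winter",
                               mean_onset = "23:30", mean_offset = "07:30",
                               wake = 150, sleep = 0.4) {
  community_profile(community, season, mean_onset, mean_offset,
                    between_person_sd = 0, within_person_sd = 0,
                    sleepless_prob = 0, offsite_prob = 0,
                    wake_activity_mean = wake, sleep_activity_mean = sleep,
                    wake_shape = Inf, sleep_shape = Inf)
}

# Minimal roster row
roster_row <- function(id, community = "housed", season = "winter",
                       gender = "female", age = 30, shift_work = FALSE) {
  data.frame(participant_id = id, community = community, season = season,
             gender = gender, age = age, shift_work = shift_work,
             stringsAsFactors = FALSE)
}

# A bare night record for QC/metric tests (clock minutes)
make_night <- function(id = "p1", date = "2023-01-09", onset = 1380,
                       offset = 420, sleepless = FALSE, excluded = FALSE,
                       reason = "none", act = 10) {
  no_sleep <- is.na(sleepless) || sleepless   # NA = unresolved candidate
  duration <- if (no_sleep) NA_real_ else (offset - onset) %% 1440
  data.frame(participant_id = id, night_date = as.Date(date),
             onset = if (no_sleep) NA_real_ else onset,
             offset = if (no_sleep) NA_real_ else offset,
             duration = duration,
             midsleep = if (no_sleep) NA_real_ else
               (onset + duration / 2) %% 1440,
             sleepless = sleepless, excluded = excluded,
             exclusion_reason = reason, in_sleep_activity = act,
             stringsAsFactors = FALSE)
}

nights_df <- function(...) do.call(rbind, list(...))

# Brute-force SRI oracle: explicit loop over epochs and consecutive days.
sri_oracle <- function(m) {
  agree <- 0L; total <- 0L
  for (d in seq_len(nrow(m) - 1)) {
    for (j in seq_len(ncol(m))) {
      if (!is.na(m[d, j]) && !is.na(m[d + 1, j])) {
        total <- total + 1L
        if (m[d, j] == m[d + 1, j]) agree <- agree + 1L
      }
    }
  }
  if (total == 0) stop("no valid pairs")
  -100 + 200 * agree / total
}
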