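#' Simulate one participant's actigraphy recording, diary, and ground truth
#'
#' Nightly true onset/offset are drawn around the profile means: a
#' person-level normal effect (SD `between_person_sd`) shared by onset and
#' offset, plus independent per-night jitter with SD
#' `within_person_sd * (1 - schedule_rigidity)`. Activity counts are gamma
#' distributed (right-skewed) with wake vs. sleep means; rigid-schedule
#' profiles get a two-peak diurnal wake modulation (morning departure,
#' evening entry). Lux is `light_transmission * outdoor solar profile`, plus
#' `evening_indoor_lux` while awake during evening hours, and 0 while
#' asleep. Diary times are truth plus symmetric heavy-tailed (t, 3 df)
#' error; entries go missing at `diary_missing_prob`, and sleepless nights
#' (wake-like activity all night) never produce a diary entry.
#'
#' @param profile a [community_profile()].
#' @param n_days number of nights to simulate (>= 1).
#' @param latitude degrees north for the daylight model (Seattle: 47.6).
#' @param seed integer seed; the recording is a pure function of it.
#' @param start_date civil date of the first recorded day.
#' @param diary_missing_prob probability a slept night has no diary entry.
#' @param diary_error_scale scale (minutes) of the t(3) diary-time error.
#' @param off_wrist_prob probability per day of one 30-120 min off-wrist gap.
#' @param epoch_length seconds per epoch (60 or 15).
#' @return list with elements `series` ([epoch_series()]), `diary`
#'   (data.frame), and `truth` (data.frame: one row per night with
#'   true_onset/true_offset clock minutes, sleepless and offsite flags).
#' @export
simulate_participant <- function(profile, n_days, latitude = 47.6, seed = 1,
                                 start_date = "2023-01-09",
                                 diary_missing_prob = 0.15,
                                 diary_error_scale = 10,
                                 off_wrist_prob = 0.02,
                                 epoch_length = 60) {
  stopifnot(n_days >= 1)
  start_date <- as.Date(start_date)
  pid <- sprintf("%s_%s_s%d", profile$community, profile$season, seed)
  set.seed(seed)

  onset_nm0 <- noon_minutes(profile$mean_onset)
  offset_nm0 <- noon_minutes(profile$mean_offset)
  if (offset_nm0 <= onset_nm0) offset_nm0 <- offset_nm0 + MIN_PER_DAY
  person <- stats::rnorm(1, 0, profile$between_person_sd)
  jit_sd <- profile$within_person_sd * (1 - profile$schedule_rigidity)

  onset_nm <- onset_nm0 + person + stats::rnorm(n_days, 0, jit_sd)
  offset_nm <- offset_nm0 + person + stats::rnorm(n_days, 0, jit_sd)
  onset_nm <- pmin(pmax(onset_nm, 300), 1020)       # 17:00 .. 05:00
  offset_nm <- pmin(pmax(offset_nm, onset_nm + 60), 1430)
  sleepless <- stats::runif(n_days) < profile$sleepless_prob
  offsite <- stats::runif(n_days) < profile$offsite_prob

  total_days <- n_days + 1L
  n_min <- total_days * MIN_PER_DAY
  asleep <- rep(FALSE, n_min)
  for (k in seq_len(n_days)) {
    if (sleepless[k]) next
    a <- (k - 1L) * MIN_PER_DAY + 720L + floor(onset_nm[k])
    b <- (k - 1L) * MIN_PER_DAY + 720L + floor(offset_nm[k])
    asleep[(a + 1L):b] <- TRUE   # 1-based epoch index: epoch m covers minute m-1
  }

  minute_of_day <- (seq_len(n_min) - 1L) %% MIN_PER_DAY
  wake_mu <- rep(profile$wake_activity_mean, n_min)
  if (profile$schedule_rigidity > 0.5) {
    # enforced departure/entry locomotion peaks around 07:30 and 21:30
    wake_mu <- wake_mu * (1 +
      1.2 * exp(-((minute_of_day - 450) / 45)^2) +
      1.2 * exp(-((minute_of_day - 1290) / 45)^2))
  }
  if (is.infinite(profile$wake_shape) && is.infinite(profile$sleep_shape)) {
    activity <- round(ifelse(asleep, profile$sleep_activity_mean, wake_mu))
  } else {
    # Sleep settles in and ends with near-immobile margins; restlessness
    # lives in the interior of the bout, with the interior mean raised so
    # the whole-bout mean equals the configured sleep_activity_mean.
    edge_min <- 20L; edge_mu <- 3
    sleep_mu <- rep(NA_real_, n_min)
    for (k in seq_len(n_days)) {
      if (sleepless[k]) next
      a <- (k - 1L) * MIN_PER_DAY + 720L + floor(onset_nm[k]) + 1L
      b <- (k - 1L) * MIN_PER_DAY + 720L + floor(offset_nm[k])
      D <- b - a + 1L
      q <- min(edge_min, D %/% 3)
      m_int <- max(profile$sleep_activity_mean,
                   (profile$sleep_activity_mean * D - edge_mu * 2 * q) /
                     max(D - 2 * q, 1))
      sleep_mu[a:b] <- m_int
      if (q > 0) {
        sleep_mu[a:(a + q - 1L)] <- edge_mu
        sleep_mu[(b - q + 1L):b] <- edge_mu
      }
    }
    mu <- ifelse(asleep, sleep_mu, wake_mu)
    shape <- ifelse(asleep, profile$sleep_shape, profile$wake_shape)
    activity <- round(stats::rgamma(n_min, shape = shape, rate = shape / mu))
  }

  dates <- start_date + seq_len(total_days) - 1L
  outdoor <- unlist(lapply(dates, solar_daylight_profile, latitude = latitude,
                           epoch_length = 60), use.names = FALSE)
  lux <- profile$light_transmission * outdoor
  evening <- minute_of_day >= 17 * 60 & minute_of_day < 23 * 60
  lux[evening & !asleep] <- lux[evening & !asleep] + profile$evening_indoor_lux
  lux[asleep] <- 0

  off_wrist <- rep(FALSE, n_min)
  gap_days <- which(stats::runif(total_days) < off_wrist_prob)
  for (d in gap_days) {
    at <- (d - 1L) * MIN_PER_DAY + sample(600:840, 1)  # daytime gap
    len <- sample(30:120, 1)
    off_wrist[at:min(at + len, n_min)] <- TRUE
  }

  series <- epoch_series(pid, as.POSIXct(paste(start_date, "00:00:00"),
                                         tz = "UTC"),
                         60L, activity, lux, off_wrist)
  if (epoch_length == 15L) {
    # expand the 60-s simulation to a 15-s grid conserving counts
    act15 <- as.vector(vapply(activity, function(a) {
      if (is.na(a)) return(rep(NA_real_, 4))
      as.numeric(stats::rmultinom(1, size = a, prob = rep(0.25, 4)))
    }, numeric(4)))
    series <- epoch_series(pid, series$start, 15L, act15,
                           rep(lux, each = 4), rep(off_wrist, each = 4))
  }

  onsite_label <- switch(profile$community,
    housed = "home", continuous_shelter = "shelter",
    overnight_shelter = "shelter", tiny_house = "tiny house", tent = "tent")
  night_dates <- start_date + seq_len(n_days) - 1L
  err <- function(n) diary_error_scale * stats::rt(n, df = 3)
  has_diary <- !sleepless & stats::runif(n_days) >= diary_missing_prob
  true_onset_clock <- noon_to_clock(onset_nm)
  true_offset_clock <- noon_to_clock(offset_nm)
  diary <- data.frame(
    participant_id = pid,
    date = night_dates[has_diary],
    bedtime = (true_onset_clock[has_diary] + err(sum(has_diary))) %% MIN_PER_DAY,
    waketime = (true_offset_clock[has_diary] + err(sum(has_diary))) %% MIN_PER_DAY,
    nap_start = NA_real_, nap_end = NA_real_,
    location = ifelse(offsite[has_diary],
                      sample(c("hotel", "friend's place", "hospital"),
                             sum(has_diary), replace = TRUE),
                      onsite_label),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    participant_id = pid,
    night_date = night_dates,
    true_onset = ifelse(sleepless, NA_real_, true_onset_clock),
    true_offset = ifelse(sleepless, NA_real_, true_offset_clock),
    true_duration = ifelse(sleepless, NA_real_, offset_nm - onset_nm),
    sleepless = sleepless,
    offsite = offsite,
    stringsAsFactors = FALSE
  )
  list(series = series, diary = diary, truth = truth)
}

#' Cohort design: which profiles, how many participants, how many nights
#'
#' @param counts named integer vector; names must match profile names
#'   (`"<community>.<season>"`), values are participant counts.
#' @param n_days named vector of recording lengths per profile (recycled
#'   scalar allowed).
#' @param profiles named list of [community_profile()]; defaults to
#'   [default_community_profiles()].
#' @param latitude degrees.
#' @param start_dates named vector (or scalar) of first recording dates per
#'   profile; defaults put winter groups in January and summer groups in
#'   July.
#' @param epoch_lengths named vector (or scalar) of recording epoch lengths
#'   in seconds per profile (default 60; 15-s recordings are brought to the
#'   common 60-s grid by the pipeline).
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(counts, n_days = 28,
                          profiles = default_community_profiles(),
                          latitude = 47.6, start_dates = NULL,
                          epoch_lengths = 60) {
  miss <- setdiff(names(counts), names(profiles))
  if (length(miss)) stop("no profile for: ", paste(miss, collapse = ", "))
  if (length(n_days) == 1L) {
    n_days <- stats::setNames(rep(n_days, length(counts)), names(counts))
  }
  if (is.null(start_dates)) {
    season <- vapply(names(counts), function(nm) profiles[[nm]]$season, "")
    start_dates <- stats::setNames(
      ifelse(season == "winter", "2023-01-09", "2022-07-11"), names(counts))
  } else if (length(start_dates) == 1L) {
    start_dates <- stats::setNames(rep(start_dates, length(counts)),
                                   names(counts))
  }
  if (length(epoch_lengths) == 1L) {
    epoch_lengths <- stats::setNames(rep(epoch_lengths, length(counts)),
                                     names(counts))
  }
  structure(list(counts = counts, n_days = n_days, profiles = profiles,
                 latitude = latitude, start_dates = start_dates,
                 epoch_lengths = epoch_lengths),
            class = "cohort_config")
}

#' Study-scale default cohort design
#'
#' Participant counts and recording lengths mirroring a two-season,
#' five-community field study: ~7-14 participants per unhoused community and
#' season recorded for 4-5 weeks, housed controls for 2 (summer) or 7
#' (winter) weeks.
#' @export
default_cohort_config <- function() {
  counts <- c(housed.summer = 10, housed.winter = 10,
              continuous_shelter.summer = 7, continuous_shelter.winter = 7,
              overnight_shelter.summer = 10, overnight_shelter.winter = 9,
              tiny_house.summer = 10, tiny_house.winter = 14,
              tent.summer = 12, tent.winter = 9)
  n_days <- c(housed.summer = 14, housed.winter = 49,
              continuous_shelter.summer = 35, continuous_shelter.winter = 28,
              overnight_shelter.summer = 28, overnight_shelter.winter = 28,
              tiny_house.summer = 35, tiny_house.winter = 28,
              tent.summer = 35, tent.winter = 28)
  # the summer overnight-shelter arm records at 15-s epochs
  epoch_lengths <- c(overnight_shelter.summer = 15)[names(counts)]
  epoch_lengths[is.na(epoch_lengths)] <- 60
  names(epoch_lengths) <- names(counts)
  cohort_config(counts, n_days, epoch_lengths = epoch_lengths)
}

#' Generate a full synthetic cohort
#'
#' Each participant gets an independent seed derived from the master seed by
#' a counter scheme (`(master * 1000003 + counter) mod (2^31 - 1)` with
#' counters assigned in sorted profile order), so the cohort is invariant to
#' the insertion order of the config and reproducible from the master seed
#' alone.
#'
#' @param config a [cohort_config()].
#' @param seed master integer seed.
#' @return list with `roster` (data.frame), `series` (named list of
#'   [epoch_series()]), `diary` (data.frame), `truth` (data.frame).
#' @export
generate_cohort <- function(config, seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  groups <- sort(names(config$counts))
  roster <- list(); series <- list(); diary <- list(); truth <- list()
  counter <- 0L
  for (g in groups) {
    prof <- config$profiles[[g]]
    for (i in seq_len(config$counts[[g]])) {
      counter <- counter + 1L
      pseed <- as.integer((seed * 1000003 + counter) %% 2147483647)
      sim <- simulate_participant(prof, n_days = config$n_days[[g]],
                                  latitude = config$latitude, seed = pseed,
                                  start_date = config$start_dates[[g]],
                                  epoch_length = config$epoch_lengths[[g]])
      pid <- sim$series$participant_id <- sprintf("%s_%02d", g, i)
      sim$diary$participant_id <- pid
      sim$truth$participant_id <- pid
      set.seed(pseed + 7L)
      if (prof$community == "overnight_shelter") {
        age <- sample(18:25, 1)       # youth shelter
      } else {
        age <- sample(20:64, 1)
      }
      gender <- sample(GENDERS, 1,
                       prob = c(0.45, 0.45, 0.04, 0.04, 0.02))
      roster[[pid]] <- data.frame(
        participant_id = pid, community = prof$community,
        season = prof$season, gender = gender, age = age,
        shift_work = FALSE, stringsAsFactors = FALSE)
      series[[pid]] <- sim$series
      diary[[pid]] <- sim$diary
      truth[[pid]] <- sim$truth
    }
  }
  list(
    roster = do.call(rbind, c(unname(roster), list(stringsAsFactors = FALSE))),
    series = series,
    diary = do.call(rbind, c(unname(diary), list(stringsAsFactors = FALSE))),
    truth = do.call(rbind, c(unname(truth), list(stringsAsFactors = FALSE)))
  )
}

#' Write a generated cohort to the standard CSV layout
#'
#' Emits `roster.csv`, `diary.csv`, `truth.csv` and one
#' `epochs_<participant>.csv` per participant, all re-readable by the
#' package's readers.
#'
#' @param cohort result of [generate_cohort()].
#' @param out_dir output directory.
#' @return named vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(roster = file.path(out_dir, "roster.csv"),
             diary = file.path(out_dir, "diary.csv"),
             truth = file.path(out_dir, "truth.csv"))
  utils::write.csv(cohort$roster[, c("participant_id", "community", "season",
                                     "gender", "age", "shift_work")],
                   paths[["roster"]], row.names = FALSE, quote = FALSE)
  dd <- cohort$diary
  dd$bedtime <- format_clock(dd$bedtime)
  dd$waketime <- format_clock(dd$waketime)
  dd$nap_start <- format_clock(dd$nap_start)
  dd$nap_end <- format_clock(dd$nap_end)
  utils::write.csv(dd, paths[["diary"]], row.names = FALSE, quote = TRUE)
  utils::write.csv(cohort$truth, paths[["truth"]], row.names = FALSE)
  for (pid in names(cohort$series)) {
    p <- file.path(out_dir, sprintf("epochs_%s.csv", pid))
    write_epoch_csv(cohort$series[[pid]], p)
    paths[[paste0("epochs_", pid)]] <- p
  }
  invisible(paths)
}
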