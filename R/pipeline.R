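#' End-to-end pipeline configuration
#'
#' Collects every analysis constant in one place: the diary-discrepancy
#' bound (3 h), the participant minimum (14 nights), the light threshold
#' (50 lux), the scoring parameters, and either a simulation design or an
#' input directory of standard CSVs.
#'
#' @param mode "simulate" or "read".
#' @param cohort_config a [cohort_config()] (simulate mode).
#' @param in_dir directory of `roster.csv`, `diary.csv`,
#'   `epochs_<id>.csv` files (read mode).
#' @param seed master seed (simulate mode).
#' @param scoring a [scoring_params()].
#' @param max_gap diary-discrepancy bound, hours.
#' @param min_nights participant inclusion minimum.
#' @param lux_threshold light-exposure threshold, lux.
#' @param location_map diary-location classification map.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("simulate", "read"),
                            cohort_config = default_cohort_config(),
                            in_dir = NULL, seed = 1,
                            scoring = scoring_params(),
                            max_gap = 3, min_nights = 14,
                            lux_threshold = 50,
                            location_map = default_location_map()) {
  mode <- match.arg(mode)
  stopifnot(max_gap > 0, min_nights > 0, lux_threshold > 0)
  if (mode == "read" && is.null(in_dir)) stop("read mode needs in_dir")
  structure(list(mode = mode, cohort_config = cohort_config,
                 in_dir = in_dir, seed = seed, scoring = scoring,
                 max_gap = max_gap, min_nights = min_nights,
                 lux_threshold = lux_threshold, location_map = location_map),
            class = "pipeline_config")
}

read_cohort_dir <- function(in_dir) {
  roster <- read_roster_csv(file.path(in_dir, "roster.csv"))
  diary <- read_diary_csv(file.path(in_dir, "diary.csv"))
  files <- list.files(in_dir, pattern = "^epochs_.*\\.csv$",
                      full.names = TRUE)
  series <- lapply(files, read_epoch_csv)
  names(series) <- vapply(series, function(s) s$participant_id, "")
  list(roster = roster, series = series, diary = diary, truth = NULL)
}

#' Run the full analysis pipeline
#'
#' Simulate or read a cohort, bring every recording to the 60-s grid, score
#' sleep, resolve sleepless nights against the diary, apply quality control,
#' aggregate per-participant sleep and light metrics and waveforms, and run
#' the group-comparison layer. With `out_dir` set, writes `nights.csv`,
#' `exclusions.csv`, `participant_summary.csv`, `waveforms.csv`,
#' `window_totals.csv`, `light_days.csv`, `stats_results.csv` and a
#' `run_log.txt` with seed and stage counts.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return list of all result tables (and the cohort's truth table when
#'   simulated).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character()
  say <- function(...) log <<- c(log, sprintf(...))
  say("seed: %s", config$seed)

  cohort <- if (config$mode == "simulate") {
    generate_cohort(config$cohort_config, seed = config$seed)
  } else {
    read_cohort_dir(config$in_dir)
  }
  say("participants: %d", nrow(cohort$roster))
  cohort$series <- lapply(cohort$series, function(s) {
    if (s$epoch_length != 60L) resample_epochs(s, 60L) else s
  })

  nights <- do.call(rbind, lapply(cohort$series, score_nights,
                                  params = config$scoring))
  rownames(nights) <- NULL
  nights <- flag_sleepless_nights(nights, cohort$diary)
  say("scored nights: %d (sleepless: %d)", nrow(nights),
      sum(nights$sleepless, na.rm = TRUE))

  qc <- qc_nights(nights, cohort$diary, cohort$roster,
                  max_gap = config$max_gap, min_nights = config$min_nights,
                  location_map = config$location_map)
  say("nights excluded: %d; participants retained: %d of %d",
      sum(qc$nights$excluded), nrow(qc$roster), nrow(cohort$roster))

  roster <- qc$roster
  summaries <- list(); light_days <- list(); waveforms <- list()
  window_totals <- list()
  for (pid in roster$participant_id) {
    s <- cohort$series[[pid]]
    pn <- qc$nights[qc$nights$participant_id == pid, , drop = FALSE]
    excl_dates <- pn$night_date[pn$excluded]
    sm <- state_matrix(s, params = config$scoring, mask_nights = excl_dates)
    sri <- tryCatch(sleep_regularity_index(sm), error = function(e) NA_real_)
    summaries[[pid]] <- participant_sleep_summary(pn, sri = sri)
    ld <- daily_light_metrics(s, threshold = config$lux_threshold)
    ld$participant_id <- pid
    light_days[[pid]] <- ld
    ls <- participant_light_summary(ld)
    names(ls) <- c("mean_first_light", "mean_last_light",
                   "mean_light_duration", "n_light_days", "n_days_exposed")
    summaries[[pid]] <- cbind(summaries[[pid]], ls)
    waveforms[[pid]] <- participant_waveform(s)
    win <- season_windows(roster$season[roster$participant_id == pid])
    window_totals[[pid]] <- data.frame(
      participant_id = pid,
      morning = window_activity_totals(s, win$morning),
      evening = window_activity_totals(s, win$evening),
      stringsAsFactors = FALSE)
  }
  summaries <- do.call(rbind, summaries)
  rownames(summaries) <- NULL
  light_days <- do.call(rbind, light_days)
  rownames(light_days) <- NULL
  window_totals <- do.call(rbind, window_totals)
  rownames(window_totals) <- NULL
  say("summaries: %d participants", nrow(summaries))

  stats_tab <- pipeline_group_stats(summaries, qc$nights, light_days,
                                    window_totals, waveforms, roster)
  say("stat results: %d rows", nrow(stats_tab))

  wf_long <- do.call(rbind, lapply(names(waveforms), function(pid) {
    data.frame(participant_id = pid,
               bin_start_min = (seq_len(WAVEFORM_BINS) - 1L) * 30,
               value = waveforms[[pid]], stringsAsFactors = FALSE)
  }))

  out <- list(nights = qc$nights, exclusions = qc$report$night_counts,
              excluded_participants = qc$report$excluded_participants,
              participant_summary = summaries, waveforms = wf_long,
              window_totals = window_totals, light_days = light_days,
              stats_results = stats_tab, roster = roster,
              truth = cohort$truth, log = log)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    wr <- function(x, f) utils::write.csv(x, file.path(out_dir, f),
                                          row.names = FALSE)
    wr(qc$nights, "nights.csv")
    wr(qc$report$night_counts, "exclusions.csv")
    wr(summaries, "participant_summary.csv")
    wr(wf_long, "waveforms.csv")
    wr(window_totals, "window_totals.csv")
    wr(light_days, "light_days.csv")
    wr(stats_tab, "stats_results.csv")
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }
  out
}

with_context <- function(res, season, outcome, test) {
  if (is.null(res) || nrow(res) == 0) return(NULL)
  cbind(data.frame(season = season, outcome = outcome, test = test,
                   stringsAsFactors = FALSE), res)
}

#' Assemble the full group-comparison table
#'
#' Per season: linear models vs. housed for the four timing parameters,
#' ANOVA + Dunnett for SRI, in-sleep activity and the intraindividual SDs,
#' Bartlett tests on timing parameters, and ANOVA on morning/evening window
#' totals plus the waveform mixed ANOVA. Across seasons: chi-squared on
#' sleepless nights and the light mixed models.
#'
#' @param summaries participant-summary table.
#' @param nights QC-filtered nights.
#' @param light_days per-day light metrics with `participant_id`.
#' @param window_totals per-participant morning/evening totals.
#' @param waveforms named list of participant waveforms.
#' @param roster included roster.
#' @return long data.frame of stat results with season/outcome/test context
#'   columns.
#' @export
pipeline_group_stats <- function(summaries, nights, light_days,
                                 window_totals, waveforms, roster) {
  res <- list()
  d <- merge(summaries, roster, by = "participant_id")
  noonize <- function(x) noon_minutes(x)
  for (season in intersect(SEASONS, unique(roster$season))) {
    ds <- d[d$season == season, , drop = FALSE]
    if (length(unique(ds$community)) < 2L || !"housed" %in% ds$community) next
    lm_out <- list(mean_onset = noonize(ds$mean_onset),
                   mean_offset = noonize(ds$mean_offset),
                   mean_midsleep = noonize(ds$mean_midsleep),
                   mean_duration = ds$mean_duration)
    for (oc in names(lm_out)) {
      vals <- data.frame(participant_id = ds$participant_id,
                         value = lm_out[[oc]])
      r <- tryCatch(suppressWarnings(fit_season_linear_model(vals, roster)),
                    error = function(e) NULL)
      res[[paste(season, oc, "lm")]] <- with_context(r, season, oc, "lm")
    }
    dunnett_out <- c("sri", "mean_in_sleep_activity", "sd_onset",
                     "sd_offset", "sd_midsleep", "sd_duration")
    for (oc in dunnett_out) {
      r <- tryCatch(suppressWarnings(
        anova_with_control_comparisons(ds[[oc]], ds$community)),
        error = function(e) NULL)
      res[[paste(season, oc, "dunnett")]] <-
        with_context(r, season, oc, "anova_dunnett")
    }
    for (oc in c("mean_onset", "mean_offset", "mean_midsleep")) {
      r <- tryCatch(variance_homogeneity_test(noonize(ds[[oc]]),
                                              ds$community),
                    error = function(e) NULL)
      res[[paste(season, oc, "bartlett")]] <-
        with_context(r, season, oc, "bartlett")
    }
    wt <- merge(window_totals, roster, by = "participant_id")
    wt <- wt[wt$season == season, , drop = FALSE]
    for (oc in c("morning", "evening")) {
      r <- tryCatch(suppressWarnings(
        anova_with_control_comparisons(wt[[oc]], wt$community)),
        error = function(e) NULL)
      res[[paste(season, oc, "window")]] <-
        with_context(r, season, paste0(oc, "_window_total"), "anova_dunnett")
    }
    wfs <- waveforms[roster$participant_id[roster$season == season]]
    wfs <- wfs[!vapply(wfs, is.null, TRUE)]
    r <- tryCatch(waveform_mixed_anova(wfs, roster), error = function(e) NULL)
    res[[paste(season, "waveform")]] <-
      with_context(r, season, "waveform", "mixed_anova")
  }

  # sleepless-night contingency across communities (seasons pooled)
  nr <- merge(nights[!nights$excluded, c("participant_id", "sleepless")],
              roster, by = "participant_id")
  tab <- table(nr$community, factor(nr$sleepless, levels = c(TRUE, FALSE)))
  if (nrow(tab) >= 2 && all(rowSums(tab) > 0)) {
    r <- tryCatch(suppressWarnings(sleepless_chi_squared(unclass(tab))),
                  error = function(e) NULL)
    res$sleepless <- with_context(r, "both", "sleepless_nights",
                                  "chi_squared")
  }

  ldm <- merge(light_days, roster, by = "participant_id")
  for (oc in c("first_time", "last_time", "duration")) {
    v <- ldm[[oc]]
    dd <- data.frame(participant_id = ldm$participant_id,
                     community = ldm$community, season = ldm$season,
                     gender = ldm$gender, value = v)
    r <- tryCatch(suppressWarnings(light_mixed_model(dd)),
                  error = function(e) NULL)
    if (!is.null(r)) {
      res[[paste("light", oc, "fixed")]] <-
        with_context(r$fixed, "both", paste0("light_", oc), "lmem")
      res[[paste("light", oc, "posthoc")]] <-
        with_context(r$posthoc, "both", paste0("light_", oc), "lmem_tukey")
    }
  }
  out <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  rownames(out) <- NULL
  out
}
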