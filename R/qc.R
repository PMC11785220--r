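#' Night-level and participant-level inclusion rules
#'
#' Three filters: diary cross-check (exclude nights where watch and diary
#' disagree by more than 3 h), off-site nights (slept away from the usual
#' site), and a participant minimum of 14 surviving nights (overnight-shift
#' workers dropped outright). Sleepless nights are observed nights and count
#' toward the 14-night minimum.
#'
#' @name quality_control
NULL

#' Cross-check watch-determined nights against diary-reported times
#'
#' A night is excluded (reason `diary_discrepancy`) when the circular
#' (mod 24 h) difference between watch onset and reported bedtime, or
#' between watch offset and reported waketime, strictly exceeds `max_gap`
#' hours. Nights with no diary entry, or with the relevant diary field
#' missing, are kept.
#'
#' @param nights night-record data.frame.
#' @param diary diary data.frame (clock minutes).
#' @param max_gap hours (default 3).
#' @return `nights` with discrepant nights marked excluded.
#' @export
crosscheck_night_with_diary <- function(nights, diary, max_gap = 3) {
  key <- paste(nights$participant_id, nights$night_date)
  dkey <- paste(diary$participant_id, diary$date)
  m <- match(key, dkey)
  bed <- diary$bedtime[m]; wake <- diary$waketime[m]
  gap_on <- abs(clock_diff_minutes(nights$onset, bed))
  gap_off <- abs(clock_diff_minutes(nights$offset, wake))
  bad <- (!is.na(gap_on) & gap_on > max_gap * 60) |
         (!is.na(gap_off) & gap_off > max_gap * 60)
  bad <- bad & !nights$excluded & !is.na(nights$onset)
  nights$excluded[bad] <- TRUE
  nights$exclusion_reason[bad] <- "diary_discrepancy"
  nights
}

#' Default diary-location classification map
#'
#' For each community, the diary location strings counted as sleeping
#' on-site, plus a shared off-site vocabulary.
#' @export
default_location_map <- function() {
  list(
    onsite = list(
      housed = c("home", "house", "apartment"),
      continuous_shelter = c("shelter", "bunkhouse"),
      overnight_shelter = c("shelter"),
      tiny_house = c("tiny house", "tiny home", "village"),
      tent = c("tent", "tent city", "encampment")
    ),
    offsite = c("hotel", "motel", "friend's place", "friend", "family",
                "hospital", "jail", "car", "outside", "street")
  )
}

#' Exclude nights slept away from the participant's usual site
#'
#' Diary locations are classified per community via the location map.
#' Off-site nights are excluded (reason `offsite`); missing locations are
#' kept; strings in neither vocabulary are kept and listed in the
#' `unmapped_locations` attribute of the result.
#'
#' @param nights night-record data.frame.
#' @param diary diary data.frame.
#' @param roster roster data.frame (participant -> community).
#' @param location_map list as returned by [default_location_map()].
#' @return `nights` with off-site nights excluded.
#' @export
filter_offsite_nights <- function(nights, diary, roster,
                                  location_map = default_location_map()) {
  key <- paste(nights$participant_id, nights$night_date)
  dkey <- paste(diary$participant_id, diary$date)
  m <- match(key, dkey)
  loc <- tolower(trimws(diary$location[m]))
  comm <- roster$community[match(nights$participant_id, roster$participant_id)]
  onsite <- mapply(function(l, cm) {
    !is.na(l) && !is.na(cm) && l %in% location_map$onsite[[cm]]
  }, loc, comm)
  offsite <- !is.na(loc) & loc %in% tolower(location_map$offsite)
  unmapped <- unique(loc[!is.na(loc) & !onsite & !offsite])
  bad <- offsite & !nights$excluded
  nights$excluded[bad] <- TRUE
  nights$exclusion_reason[bad] <- "offsite"
  attr(nights, "unmapped_locations") <- unmapped
  nights
}

#' Apply the participant-level inclusion rules
#'
#' Participants keep their place in the analysis only with at least
#' `min_nights` surviving (non-excluded) nights; sleepless nights are
#' observed nights and count. Participants flagged as overnight-shift
#' workers are dropped regardless.
#'
#' @param nights night-record data.frame after night-level filters.
#' @param roster roster data.frame (optionally with `shift_work`).
#' @param min_nights minimum surviving nights (default 14).
#' @return list with `roster` (included participants), `nights` (nights of
#'   included participants), and `report` (an exclusion-report list).
#' @export
apply_participant_inclusion <- function(nights, roster, min_nights = 14) {
  surv <- tapply(!nights$excluded, nights$participant_id, sum)
  surv_n <- as.integer(surv[roster$participant_id])
  surv_n[is.na(surv_n)] <- 0L
  shift <- if ("shift_work" %in% names(roster)) roster$shift_work else
    rep(FALSE, nrow(roster))
  drop <- surv_n < min_nights | shift
  reason <- ifelse(shift, "shift_work", "too_few_nights")[drop]
  keep_ids <- roster$participant_id[!drop]
  report <- exclusion_report(nights, roster,
                             excluded_participants = data.frame(
                               participant_id = roster$participant_id[drop],
                               reason = reason,
                               surviving_nights = surv_n[drop],
                               stringsAsFactors = FALSE))
  list(
    roster = roster[!drop, , drop = FALSE],
    nights = nights[nights$participant_id %in% keep_ids, , drop = FALSE],
    report = report
  )
}

#' Build an exclusion report
#'
#' Per-participant counts of excluded nights by reason and of surviving
#' nights; excluded + surviving always reconciles with total nights.
#'
#' @param nights night-record data.frame.
#' @param roster roster data.frame.
#' @param excluded_participants data.frame of dropped participants.
#' @return list with `night_counts` (data.frame) and
#'   `excluded_participants`.
#' @export
exclusion_report <- function(nights, roster,
                             excluded_participants = NULL) {
  tab <- table(nights$participant_id, nights$exclusion_reason)
  ids <- rownames(tab)
  nc <- data.frame(
    participant_id = ids,
    total_nights = as.integer(table(nights$participant_id)[ids]),
    stringsAsFactors = FALSE
  )
  for (r in c("diary_discrepancy", "offsite", "missing_data")) {
    nc[[r]] <- if (r %in% colnames(tab)) as.integer(tab[, r]) else 0L
  }
  nc$surviving <- nc$total_nights - nc$diary_discrepancy - nc$offsite -
    nc$missing_data
  list(night_counts = nc, excluded_participants = excluded_participants)
}

#' Run the full night- and participant-level QC
#'
#' @param nights scored nights (after [flag_sleepless_nights()]).
#' @param diary diary data.frame.
#' @param roster roster data.frame.
#' @param max_gap diary-discrepancy bound in hours.
#' @param min_nights participant minimum surviving nights.
#' @param location_map see [default_location_map()].
#' @return list with filtered `nights`, `roster`, and `report`.
#' @export
qc_nights <- function(nights, diary, roster, max_gap = 3, min_nights = 14,
                      location_map = default_location_map()) {
  nights <- crosscheck_night_with_diary(nights, diary, max_gap)
  nights <- filter_offsite_nights(nights, diary, roster, location_map)
  apply_participant_inclusion(nights, roster, min_nights)
}
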