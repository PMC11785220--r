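#' Read an epoch-level actigraphy export
#'
#' Expects a delimited text file with columns `timestamp` (ISO 8601, local
#' civil time), `activity` (counts/epoch), `white_light_lux` (lux) and an
#' optional `off_wrist` (0/1) column. The epoch length is inferred from the
#' timestamp spacing and must be uniform.
#'
#' @param path file path.
#' @param sep field separator (default comma).
#' @return an [epoch_series()].
#' @export
read_epoch_csv <- function(path, sep = ",") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("timestamp", "activity", "white_light_lux")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  ts <- as.POSIXct(df$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  if (anyNA(ts)) {
    stop("unparseable timestamp at row ", which(is.na(ts))[1])
  }
  d <- diff(as.numeric(ts))
  if (length(d)) {
    bad <- which(d <= 0)
    if (length(bad)) {
      stop("timestamps not strictly increasing at row ", bad[1] + 1L)
    }
    if (length(unique(d)) != 1L) {
      stop("irregular timestamp spacing at row ",
           which(d != d[1])[1] + 1L)
    }
    epoch_len <- d[1]
  } else {
    epoch_len <- 60
  }
  pid <- if ("participant_id" %in% names(df)) df$participant_id[1] else
    sub("\\.[^.]*$", "", basename(path))
  ow <- if ("off_wrist" %in% names(df)) as.logical(df$off_wrist) else
    rep(FALSE, nrow(df))
  epoch_series(pid, ts[1], epoch_len, df$activity, df$white_light_lux, ow)
}

#' Write an epoch series to the standard CSV layout
#' @param series an `epoch_series`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_epoch_csv <- function(series, path) {
  df <- data.frame(
    participant_id = series$participant_id,
    timestamp = format(epoch_times(series), "%Y-%m-%dT%H:%M:%S"),
    activity = ifelse(series$off_wrist, 0, series$activity),
    white_light_lux = ifelse(series$off_wrist, 0, series$lux),
    off_wrist = as.integer(series$off_wrist)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sleep-diary CSV
#'
#' Columns: `participant_id, date, bedtime, waketime, nap_start, nap_end,
#' location`. Blank fields become NA. Clock fields are parsed to minutes
#' after midnight. At most one entry per participant per date.
#'
#' @param path file path.
#' @return a data.frame of diary entries.
#' @export
read_diary_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("participant_id", "date")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  key <- paste(df$participant_id, df$date)
  if (anyDuplicated(key)) {
    stop("duplicate diary entries for: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  blank_na <- function(x) ifelse(is.na(x) | !nzchar(trimws(x)), NA, x)
  data.frame(
    participant_id = df$participant_id,
    date = as.Date(df$date),
    bedtime = parse_clock(blank_na(df$bedtime %||% NA)),
    waketime = parse_clock(blank_na(df$waketime %||% NA)),
    nap_start = parse_clock(blank_na(df$nap_start %||% NA)),
    nap_end = parse_clock(blank_na(df$nap_end %||% NA)),
    location = as.character(blank_na(df$location %||% NA)),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

COMMUNITIES <- c("housed", "continuous_shelter", "overnight_shelter",
                 "tiny_house", "tent")
SEASONS <- c("summer", "winter")
GENDERS <- c("female", "male", "nonbinary", "trans", "other")

#' Read a participant roster CSV
#'
#' Columns: `participant_id, community, season, gender, age`, optionally
#' `shift_work` (0/1; overnight-shift workers are dropped by
#' [apply_participant_inclusion()]). Community, season and gender labels must
#' come from the closed vocabularies.
#'
#' @param path file path.
#' @return a data.frame with factor-checked columns.
#' @export
read_roster_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "community", "season", "gender", "age")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  chk <- function(x, vocab, what) {
    bad <- setdiff(unique(x), vocab)
    if (length(bad)) stop("unknown ", what, " label(s): ",
                          paste(bad, collapse = ", "))
    x
  }
  data.frame(
    participant_id = as.character(df$participant_id),
    community = chk(df$community, COMMUNITIES, "community"),
    season = chk(df$season, SEASONS, "season"),
    gender = chk(df$gender, GENDERS, "gender"),
    age = as.numeric(df$age),
    shift_work = if ("shift_work" %in% names(df)) df$shift_work == 1 else
      rep(FALSE, nrow(df)),
    stringsAsFactors = FALSE
  )
}

#' Write the derived result tables
#'
#' One CSV per table with a fixed column order; reals keep full precision so
#' a write/read round trip reproduces values to at least 6 significant
#' digits. Writing the same inputs twice is byte-identical.
#'
#' @param nights data.frame of night records (may be empty).
#' @param summaries data.frame of participant summaries.
#' @param stats data.frame of statistical results.
#' @param out_dir output directory, created if absent.
#' @return named character vector of file paths.
#' @export
write_tables <- function(nights, summaries, stats, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- c(
    nights = file.path(out_dir, "nights.csv"),
    participant_summary = file.path(out_dir, "participant_summary.csv"),
    stats_results = file.path(out_dir, "stats_results.csv")
  )
  utils::write.csv(nights, paths[["nights"]], row.names = FALSE)
  utils::write.csv(summaries, paths[["participant_summary"]], row.names = FALSE)
  utils::write.csv(stats, paths[["stats_results"]], row.names = FALSE)
  paths
}
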