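#' Read a hip-device epoch stream
#'
#' Parses a CSV of fixed-epoch accelerometer records (one row per epoch) with
#' columns `participant_id`, `timestamp` (ISO-8601 local clock time; no
#' timezone conversion is performed), `activity_count` and `step_count`.
#' Timestamps must be strictly increasing within each participant and evenly
#' spaced at `expected_epoch_s` seconds.
#'
#' @param path Path to a CSV file.
#' @param expected_epoch_s Expected epoch length in seconds (30 or 60 for
#'   typical hip accelerometers).
#' @return A tibble with columns `participant_id` (character), `timestamp`
#'   (POSIXct, UTC-encoded local clock), `activity_count` and `step_count`
#'   (integer), sorted by participant and time, with attribute `epoch_s`.
#' @export
read_hip_epochs <- function(path, expected_epoch_s = 30L) {
  expected_epoch_s <- assert_count(expected_epoch_s, "expected_epoch_s")
  if (!file.exists(path)) stop_input("file not found: ", path)
  x <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      timestamp = readr::col_datetime(format = ""),
      activity_count = readr::col_double(),
      step_count = readr::col_double()
    ),
    progress = FALSE
  )
  assert_cols(x, c("participant_id", "timestamp", "activity_count", "step_count"),
              "hip epoch file")
  x <- dplyr::arrange(x, .data$participant_id, .data$timestamp)
  validate_epoch_stream(x, expected_epoch_s)
  x$activity_count <- as.integer(x$activity_count)
  x$step_count <- as.integer(x$step_count)
  attr(x, "epoch_s") <- expected_epoch_s
  x
}

validate_epoch_stream <- function(x, expected_epoch_s) {
  if (nrow(x) == 0L) return(invisible(x))
  if (any(is.na(x$timestamp))) {
    stop_input("unparseable timestamp at row ", which(is.na(x$timestamp))[1L])
  }
  assert_nonneg_int(x$activity_count, "activity_count")
  assert_nonneg_int(x$step_count, "step_count")
  by_p <- split(x$timestamp, x$participant_id)
  for (pid in names(by_p)) {
    ts <- by_p[[pid]]
    if (length(ts) < 2L) next
    d <- diff(as.numeric(ts))
    if (any(d == 0)) {
      stop_input(sprintf(
        "duplicate timestamp for participant '%s' at %s",
        pid, format(ts[which(d == 0)[1L] + 1L], "%Y-%m-%dT%H:%M:%S")
      ))
    }
    # gaps between wear periods are allowed; spacing must be a multiple of
    # the epoch, and at least one pair must sit at the nominal spacing
    if (any(d %% expected_epoch_s != 0)) {
      bad <- which(d %% expected_epoch_s != 0)[1L]
      stop_input(sprintf(
        "irregular epoch spacing (%ds) for participant '%s' at %s; expected multiples of %ds",
        d[bad], pid, format(ts[bad + 1L], "%Y-%m-%dT%H:%M:%S"), expected_epoch_s
      ))
    }
  }
  invisible(x)
}

#' Write a hip-device epoch stream
#'
#' Inverse of [read_hip_epochs()]; values round-trip exactly.
#'
#' @param x Tibble of epoch records.
#' @param path Output CSV path.
#' @export
write_hip_epochs <- function(x, path) {
  assert_cols(x, c("participant_id", "timestamp", "activity_count", "step_count"),
              "hip epoch table")
  out <- tibble::tibble(
    participant_id = x$participant_id,
    timestamp = format(x$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    activity_count = x$activity_count,
    step_count = x$step_count
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a wrist-device hourly stream
#'
#' Parses a CSV with columns `participant_id`, `date` (ISO-8601), `hour`
#' (0-23), `step_count` and `hr_sample_count`. An empty `step_count` cell is
#' parsed as missing (`NA`), which is distinct from 0 everywhere downstream:
#' hours with missing steps are excluded from analysis, never zero-counted.
#'
#' @param path Path to a CSV file.
#' @return A tibble with one row per (participant, date, hour).
#' @export
read_watch_hours <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  x <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      date = readr::col_date(format = "%Y-%m-%d"),
      hour = readr::col_double(),
      step_count = readr::col_double(),
      hr_sample_count = readr::col_double()
    ),
    progress = FALSE
  )
  assert_cols(x, c("participant_id", "date", "hour", "step_count", "hr_sample_count"),
              "watch hourly file")
  validate_watch_hours(x)
  x$hour <- as.integer(x$hour)
  x$step_count <- as.integer(x$step_count)
  x$hr_sample_count <- as.integer(x$hr_sample_count)
  dplyr::arrange(x, .data$participant_id, .data$date, .data$hour)
}

validate_watch_hours <- function(x) {
  if (nrow(x) == 0L) return(invisible(x))
  if (any(is.na(x$hour) | x$hour < 0 | x$hour > 23 | x$hour != floor(x$hour))) {
    bad <- which(is.na(x$hour) | x$hour < 0 | x$hour > 23 | x$hour != floor(x$hour))[1L]
    stop_input(sprintf("hour out of range 0-23 at row %d (value %s)",
                       bad, format(x$hour[bad])))
  }
  assert_nonneg_int(x$step_count, "step_count", allow_na = TRUE)
  assert_nonneg_int(x$hr_sample_count, "hr_sample_count")
  key <- paste(x$participant_id, x$date, x$hour, sep = "\r")
  if (anyDuplicated(key)) {
    d <- x[duplicated(key), ][1L, ]
    stop_input(sprintf(
      "duplicate record for participant '%s' on %s hour %d",
      d$participant_id, format(d$date), d$hour
    ))
  }
  invisible(x)
}

#' Write a wrist-device hourly stream
#'
#' Inverse of [read_watch_hours()]; missing step counts are written as empty
#' cells and round-trip as `NA`.
#'
#' @param x Tibble of hourly records.
#' @param path Output CSV path.
#' @export
write_watch_hours <- function(x, path) {
  assert_cols(x, c("participant_id", "date", "hour", "step_count", "hr_sample_count"),
              "watch hourly table")
  readr::write_csv(x, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a participant covariate roster
#'
#' Parses a CSV with columns `participant_id`, `age` (years), `sex`
#' (`female`/`male`), `cohort`, `height` (inches), `bmi` (kg/m^2),
#' `mobility_limitation`, `in_eastern_time` and optionally `obesity`. When
#' the obesity column is absent (or a cell is empty) it is derived as
#' BMI >= 30; when present it must be consistent with BMI.
#'
#' @param path Path to a CSV file.
#' @return A tibble with one row per participant.
#' @export
read_roster <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  x <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    sex = readr::col_character(),
    cohort = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  assert_cols(x, c("participant_id", "age", "sex", "cohort", "height", "bmi",
                   "mobility_limitation", "in_eastern_time"), "roster file")
  if (anyDuplicated(x$participant_id)) {
    stop_input("duplicate participant_id in roster: ",
               x$participant_id[duplicated(x$participant_id)][1L])
  }
  if (any(is.na(x$bmi) | x$bmi <= 0)) {
    stop_input("bmi must be positive for all participants")
  }
  if (!all(x$sex %in% c("female", "male"))) {
    stop_input("sex must be 'female' or 'male'")
  }
  derived <- x$bmi >= 30
  if (!"obesity" %in% names(x)) {
    x$obesity <- derived
  } else {
    x$obesity <- as.logical(x$obesity)
    x$obesity[is.na(x$obesity)] <- derived[is.na(x$obesity)]
    if (any(x$obesity != derived)) {
      stop_input("obesity flag inconsistent with BMI >= 30 for participant: ",
                 x$participant_id[which(x$obesity != derived)[1L]])
    }
  }
  x$mobility_limitation <- as.logical(x$mobility_limitation)
  x$in_eastern_time <- as.logical(x$in_eastern_time)
  dplyr::relocate(
    dplyr::arrange(x, .data$participant_id),
    "participant_id", "age", "sex", "cohort", "height", "bmi",
    "obesity", "mobility_limitation", "in_eastern_time"
  )
}

#' Write a participant roster
#'
#' @param x Roster tibble.
#' @param path Output CSV path.
#' @export
write_roster <- function(x, path) {
  x <- dplyr::mutate(x, dplyr::across(dplyr::where(is.logical), as.integer))
  readr::write_csv(x, path, na = "", progress = FALSE)
  invisible(path)
}

#' Write an agreement report to disk
#'
#' Writes the statistics table as a tidy CSV (one row per statistic with
#' columns sample, subgroup, statistic, estimate, ci_low, ci_high,
#' n_participants, n_units) and a JSON sidecar (`<path>.json`) carrying the
#' configuration, the exclusion ledger and any extra detail (contingency
#' tables, variance components). Output is byte-identical across re-runs with
#' the same inputs.
#'
#' @param report An `agreement_report` object (see [run_pipeline()]), or any
#'   list with a `stats` tibble and optional `config`, `ledger`, `details`.
#' @param path Output CSV path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stats_tbl <- report$stats
  if (is.null(stats_tbl)) stop_input("report has no 'stats' table")
  cols <- c("sample", "subgroup", "statistic", "estimate", "ci_low", "ci_high",
            "n_participants", "n_units")
  assert_cols(stats_tbl, cols, "report stats table")
  readr::write_csv(stats_tbl[cols], path, na = "", progress = FALSE)
  sidecar <- sanitize_for_json(list(
    config = report$config %||% list(),
    ledger = if (!is.null(report$ledger)) as.data.frame(report$ledger) else list(),
    details = report$details %||% list()
  ))
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

# make nested detail objects (contingency tables, dates, S3 lists)
# serializable by jsonlite
sanitize_for_json <- function(x) {
  if (inherits(x, "table")) {
    return(list(counts = unclass(unname(x)), dimnames = dimnames(x)))
  }
  if (inherits(x, c("Date", "POSIXct"))) return(format(x))
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(unclass(x), sanitize_for_json))
  x
}
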