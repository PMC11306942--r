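#' Reintegrate accelerometer epochs to a coarser epoch length
#'
#' Sums activity counts and steps from fine epochs (e.g. 30 s) into aligned
#' coarser epochs (e.g. 60 s for nonwear detection). Output epochs are aligned
#' to clock boundaries (an output epoch starts at a timestamp divisible by
#' `out_epoch_s`); totals are conserved exactly.
#'
#' @param x Epoch tibble from [read_hip_epochs()] (or the same shape).
#' @param out_epoch_s Output epoch length in seconds; must be a multiple of
#'   the input epoch length.
#' @param epoch_s Input epoch length in seconds; defaults to the stream's
#'   `epoch_s` attribute.
#' @return An epoch tibble at the coarser resolution with attribute `epoch_s`.
#' @export
reintegrate_epochs <- function(x, out_epoch_s, epoch_s = attr(x, "epoch_s")) {
  out_epoch_s <- assert_count(out_epoch_s, "out_epoch_s")
  if (is.null(epoch_s)) stop_input("input epoch length unknown; pass epoch_s")
  epoch_s <- assert_count(epoch_s, "epoch_s")
  if (out_epoch_s %% epoch_s != 0L) {
    stop_input(sprintf(
      "out_epoch_s (%d) must be an integer multiple of the input epoch (%d s)",
      out_epoch_s, epoch_s
    ))
  }
  if (nrow(x) == 0L) {
    attr(x, "epoch_s") <- out_epoch_s
    return(x)
  }
  secs <- as.numeric(x$timestamp)
  if (any(secs %% epoch_s != 0)) {
    stop_input("timestamps are not aligned to the input epoch grid")
  }
  bucket <- secs - secs %% out_epoch_s
  out <- dplyr::summarise(
    dplyr::group_by(
      tibble::tibble(
        participant_id = x$participant_id,
        timestamp = as.POSIXct(bucket, origin = "1970-01-01", tz = "UTC"),
        activity_count = x$activity_count,
        step_count = x$step_count
      ),
      .data$participant_id, .data$timestamp
    ),
    activity_count = sum(.data$activity_count),
    step_count = sum(.data$step_count),
    .groups = "drop"
  )
  out <- dplyr::arrange(out, .data$participant_id, .data$timestamp)
  attr(out, "epoch_s") <- out_epoch_s
  out
}

#' Parameters for Choi nonwear detection
#'
#' @param window_min Minimum nonwear run length in minutes (default 90).
#' @param spike_tolerance_min Maximum consecutive nonzero minutes tolerated
#'   inside a nonwear run (default 2).
#' @param flank_min Minimum zero-count minutes required on both sides of a
#'   tolerated spike (default 30).
#' @return A validated `choi_params` list.
#' @export
choi_params <- function(window_min = 90L, spike_tolerance_min = 2L,
                        flank_min = 30L) {
  window_min <- assert_count(window_min, "window_min")
  spike_tolerance_min <- assert_count(spike_tolerance_min, "spike_tolerance_min")
  flank_min <- assert_count(flank_min, "flank_min")
  if (flank_min >= window_min) stop_input("flank_min must be < window_min")
  structure(list(window_min = window_min,
                 spike_tolerance_min = spike_tolerance_min,
                 flank_min = flank_min),
            class = "choi_params")
}

#' Detect nonwear minutes with the Choi algorithm
#'
#' A minute is classified nonwear when it lies inside a run of at least
#' `window_min` minutes of zero activity counts, where runs may absorb
#' nonzero "spikes" of up to `spike_tolerance_min` consecutive minutes
#' provided each spike is flanked by at least `flank_min` minutes of zeros
#' immediately before and after it. All other minutes are wear.
#'
#' @param counts Integer vector of per-minute activity counts (reintegrate
#'   30 s epochs to 60 s first).
#' @param params A [choi_params()] list.
#' @return Logical vector, `TRUE` where the minute is worn.
#' @export
detect_nonwear_choi <- function(counts, params = choi_params()) {
  if (!inherits(params, "choi_params")) params <- do.call(choi_params, params)
  n <- length(counts)
  if (n == 0L) return(logical(0))
  if (any(is.na(counts) | counts < 0)) {
    stop_input("activity counts must be non-negative and non-missing")
  }
  r <- rle(counts == 0)
  k <- length(r$lengths)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  wear <- rep(TRUE, n)

  i <- 1L
  while (i <= k) {
    if (!r$values[i]) { i <- i + 1L; next }   # seek next zero run
    # grow a candidate nonwear segment: zero run i, absorbing qualifying
    # spike + zero-run pairs
    j <- i
    while (j + 2L <= k &&
           !r$values[j + 1L] &&
           r$lengths[j + 1L] <= params$spike_tolerance_min &&
           r$lengths[j] >= params$flank_min &&
           r$lengths[j + 2L] >= params$flank_min) {
      j <- j + 2L
    }
    seg_len <- run_end[j] - run_start[i] + 1L
    if (seg_len >= params$window_min) {
      wear[run_start[i]:run_end[j]] <- FALSE
    }
    i <- j + 1L
  }
  wear
}

#' Expand a hip epoch stream to a complete per-minute grid
#'
#' Reintegrates to 60 s epochs and lays the records on a complete
#' minute-of-day grid per participant-date (absent minutes get zero counts,
#' matching a device that records zeros off-body).
#'
#' @param x Epoch tibble (30 or 60 s).
#' @param epoch_s Input epoch length; defaults to the `epoch_s` attribute.
#' @return Tibble with columns participant_id, date, minute (0-1439),
#'   activity_count, step_count.
#' @export
hip_minute_grid <- function(x, epoch_s = attr(x, "epoch_s")) {
  m <- reintegrate_epochs(x, 60L, epoch_s = epoch_s)
  if (nrow(m) == 0L) {
    return(tibble::tibble(participant_id = character(), date = as.Date(character()),
                          minute = integer(), activity_count = integer(),
                          step_count = integer()))
  }
  secs <- as.numeric(m$timestamp)
  day <- floor(secs / 86400)
  minute <- as.integer((secs %% 86400) / 60)
  obs <- tibble::tibble(
    participant_id = m$participant_id, day = day, minute = minute,
    activity_count = m$activity_count, step_count = m$step_count
  )
  grid <- tidyr::expand_grid(
    dplyr::distinct(obs, .data$participant_id, .data$day),
    minute = 0:1439
  )
  out <- dplyr::left_join(grid, obs, by = c("participant_id", "day", "minute"))
  out$activity_count[is.na(out$activity_count)] <- 0L
  out$step_count[is.na(out$step_count)] <- 0L
  out$date <- as.Date(out$day, origin = "1970-01-01")
  out <- dplyr::arrange(out, .data$participant_id, .data$date, .data$minute)
  out[c("participant_id", "date", "minute", "activity_count", "step_count")]
}

#' Restrict a per-minute mask to the daily possible-wear window
#'
#' Hip-device processing removes a nightly block of clock hours, leaving (by
#' default) 18 hours of possible wear per day; minutes outside the window
#' contribute neither wear time nor steps to daily summaries.
#'
#' @param minutes Minute grid (see [hip_minute_grid()]) with a logical `wear`
#'   column.
#' @param window Length-2 integer vector `c(start_hour, end_hour)` of the
#'   allowed window, interpreted as `[start, end)` on the 24 h clock; default
#'   `c(6, 24)` (00:00-06:00 removed).
#' @return The input with `wear` forced `FALSE` (and an `in_window` flag)
#'   outside the window.
#' @export
apply_daily_window <- function(minutes, window = c(6L, 24L)) {
  if (length(window) != 2L || window[1] < 0 || window[2] > 24 ||
      window[1] >= window[2]) {
    stop_input("window must be c(start_hour, end_hour) with 0 <= start < end <= 24")
  }
  hour <- minutes$minute %/% 60L
  minutes$in_window <- hour >= window[1] & hour < window[2]
  if ("wear" %in% names(minutes)) {
    minutes$wear <- minutes$wear & minutes$in_window
  }
  minutes
}

#' Build hip hour cells from a worn minute grid
#'
#' Aggregates the Choi wear mask and step counts into one cell per
#' participant-date-hour. Steps in Choi-nonwear minutes or outside the daily
#' window are excluded. The block-rule wear flag for the hip device is
#' "any hour with >0 step count".
#'
#' @param minutes Minute grid with logical `wear` (already windowed via
#'   [apply_daily_window()]).
#' @return Hour-cell tibble: participant_id, date, hour, device = "hip",
#'   steps, wear_minutes, wear_daily_rule, wear_block_rule.
#' @export
hip_hour_cells <- function(minutes) {
  assert_cols(minutes, c("participant_id", "date", "minute", "step_count", "wear"),
              "minute grid")
  minutes$hour <- minutes$minute %/% 60L
  out <- dplyr::summarise(
    dplyr::group_by(minutes, .data$participant_id, .data$date, .data$hour),
    steps = sum(.data$step_count[.data$wear]),
    wear_minutes = sum(.data$wear),
    .groups = "drop"
  )
  out$device <- "hip"
  out$hr_sample_count <- NA_integer_
  out$wear_daily_rule <- out$wear_minutes > 0L
  out$wear_block_rule <- out$steps > 0L
  out[c("participant_id", "date", "hour", "device", "steps", "hr_sample_count",
        "wear_minutes", "wear_daily_rule", "wear_block_rule")]
}

#' Build wrist hour cells from hourly watch records
#'
#' Applies the two wrist wear rules exactly as stated for the source device:
#' the daily-accumulation rule counts an hour as worn when it has at least
#' `hr_min` heart-rate samples or at least `steps_min` steps; the
#' block-overlap rule counts an hour when it has more than `steps_min` steps,
#' or 0-`steps_min` steps with at least `hr_min` heart-rate samples. Hours
#' with missing step counts never satisfy the block rule (they are excluded
#' from overlap blocks) but can satisfy the daily rule via heart rate.
#'
#' @param records Watch hourly tibble from [read_watch_hours()].
#' @param steps_min Step threshold in both rules (default 30).
#' @param hr_min Minimum heart-rate samples (default 2).
#' @return Hour-cell tibble with the same columns as [hip_hour_cells()]
#'   (`device = "wrist"`, `wear_minutes` is `NA`).
#' @export
wrist_hour_cells <- function(records, steps_min = 30L, hr_min = 2L) {
  assert_cols(records, c("participant_id", "date", "hour", "step_count",
                         "hr_sample_count"), "watch records")
  steps <- records$step_count
  hr <- records$hr_sample_count
  daily <- (hr >= hr_min) | (!is.na(steps) & steps >= steps_min)
  block <- !is.na(steps) & (steps > steps_min | (steps <= steps_min & hr >= hr_min))
  tibble::tibble(
    participant_id = records$participant_id,
    date = records$date,
    hour = as.integer(records$hour),
    device = "wrist",
    steps = steps,
    hr_sample_count = hr,
    wear_minutes = NA_integer_,
    wear_daily_rule = daily,
    wear_block_rule = block
  )
}

#' Summarize hour cells into person-days
#'
#' Hip wear hours are worn minutes / 60 (fractional, within the daily
#' window); wrist wear hours are the count of daily-rule wear hours. Daily
#' step totals sum non-missing steps. A valid day has at least
#' `min_wear_hours` wear hours.
#'
#' @param cells Hour-cell tibble (one device, or mixed with a `device`
#'   column).
#' @param min_wear_hours Valid-day threshold in hours (default 10).
#' @return Person-day tibble: participant_id, date, device, wear_hours,
#'   total_steps, is_valid.
#' @export
summarize_person_days <- function(cells, min_wear_hours = 10) {
  assert_cols(cells, c("participant_id", "date", "device", "steps",
                       "wear_minutes", "wear_daily_rule"), "hour cells")
  out <- dplyr::summarise(
    dplyr::group_by(cells, .data$participant_id, .data$date, .data$device),
    wear_hours = if (dplyr::first(.data$device) == "hip") {
      sum(.data$wear_minutes) / 60
    } else {
      as.numeric(sum(.data$wear_daily_rule))
    },
    total_steps = sum(.data$steps[!is.na(.data$steps)]),
    .groups = "drop"
  )
  out$is_valid <- out$wear_hours >= min_wear_hours
  out
}

#' Keep participants with enough valid days
#'
#' Per device, retains participants with at least `min_days` valid days
#' (>= 10 h wear), recording removals in an exclusion ledger.
#'
#' @param person_days Person-day tibble (may mix devices).
#' @param min_days Minimum number of valid days (default 3).
#' @return List with `person_days` (filtered) and `ledger`.
#' @export
filter_valid_participants <- function(person_days, min_days = 3L) {
  min_days <- assert_count(min_days, "min_days", min = 1L)
  ledger <- ledger_new()
  keep <- dplyr::summarise(
    dplyr::group_by(person_days, .data$device, .data$participant_id),
    n_valid = sum(.data$is_valid), .groups = "drop"
  )
  keep$ok <- keep$n_valid >= min_days
  out <- dplyr::semi_join(
    person_days,
    keep[keep$ok, c("device", "participant_id")],
    by = c("device", "participant_id")
  )
  for (dev in unique(person_days$device)) {
    kd <- keep[keep$device == dev, ]
    removed <- kd$participant_id[!kd$ok]
    n_units <- sum(person_days$device == dev &
                     person_days$participant_id %in% removed)
    ledger <- ledger_add(
      ledger, stage = paste0("valid_participants_", dev),
      rule = sprintf(">=%d valid days (>=10 h wear)", min_days),
      n_participants_removed = length(removed), n_units_removed = n_units
    )
  }
  list(person_days = out, ledger = ledger)
}

# ---- exclusion ledger helpers ------------------------------------------

#' Create an empty exclusion ledger
#' @return Zero-row ledger tibble.
#' @export
ledger_new <- function() {
  tibble::tibble(stage = character(), rule = character(),
                 n_participants_removed = integer(), n_units_removed = integer())
}

#' Append one event to an exclusion ledger
#' @param ledger Ledger tibble.
#' @param stage,rule Stage identifier and human-readable rule.
#' @param n_participants_removed,n_units_removed Counts removed at this stage.
#' @return The extended ledger.
#' @export
ledger_add <- function(ledger, stage, rule, n_participants_removed = 0L,
                       n_units_removed = 0L) {
  dplyr::bind_rows(ledger, tibble::tibble(
    stage = stage, rule = rule,
    n_participants_removed = as.integer(n_participants_removed),
    n_units_removed = as.integer(n_units_removed)
  ))
}
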