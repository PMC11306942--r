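#' Build the same-date paired person-day sample (sample 1)
#'
#' Inner-joins hip and wrist person-days on (participant, date), keeping only
#' dates valid (>= 10 h wear) on both devices; dates on which only one device
#' was worn are excluded. Input person-days should already pass
#' [filter_valid_participants()] per device.
#'
#' @param hip_days,wrist_days Person-day tibbles for each device.
#' @return List with `pairs` (participant_id, date, steps_hip, steps_wrist,
#'   wear_hours_hip, wear_hours_wrist, wear_diff) and `ledger`.
#' @export
build_sample1 <- function(hip_days, wrist_days) {
  hip <- hip_days[hip_days$is_valid, ]
  wrist <- wrist_days[wrist_days$is_valid, ]
  pairs <- dplyr::inner_join(
    dplyr::select(hip, "participant_id", "date",
                  steps_hip = "total_steps", wear_hours_hip = "wear_hours"),
    dplyr::select(wrist, "participant_id", "date",
                  steps_wrist = "total_steps", wear_hours_wrist = "wear_hours"),
    by = c("participant_id", "date")
  )
  pairs$wear_diff <- abs(pairs$wear_hours_wrist - pairs$wear_hours_hip)
  pairs <- dplyr::arrange(pairs, .data$participant_id, .data$date)
  pool <- union(hip$participant_id, wrist$participant_id)
  ledger <- ledger_add(
    ledger_new(), "sample1_pairing",
    "same-date pairs with >=10 h wear on both devices",
    n_participants_removed = length(setdiff(pool, pairs$participant_id)),
    n_units_removed = (sum(hip_days$is_valid) + sum(wrist_days$is_valid)) -
      2L * nrow(pairs)
  )
  list(pairs = pairs, ledger = ledger)
}

#' Find trimmed overlap blocks of joint wear
#'
#' Within each participant-date (midnight to midnight), finds maximal runs of
#' consecutive clock hours in which both devices satisfy their block-rule
#' wear definitions (which already excludes wrist hours with missing steps).
#' Runs shorter than `min_block_h` hours are discarded; the first and last
#' hour of each surviving run are dropped (they may be partial hours) and the
#' interior hours are returned as paired person-hours.
#'
#' @param hip_cells,wrist_cells Hour-cell tibbles from [hip_hour_cells()] and
#'   [wrist_hour_cells()]; any number of participant-dates.
#' @param min_block_h Minimum block length in hours (default 3).
#' @param trim_h Hours trimmed from each end of a block (default 1).
#' @return Paired-hour tibble: participant_id, date, hour, steps_hip,
#'   steps_wrist, block_id.
#' @export
find_overlap_blocks <- function(hip_cells, wrist_cells, min_block_h = 3L,
                                trim_h = 1L) {
  min_block_h <- assert_count(min_block_h, "min_block_h")
  trim_h <- assert_count(trim_h, "trim_h", min = 0L)
  joint <- dplyr::inner_join(
    dplyr::select(hip_cells, "participant_id", "date", "hour",
                  steps_hip = "steps", wear_hip = "wear_block_rule"),
    dplyr::select(wrist_cells, "participant_id", "date", "hour",
                  steps_wrist = "steps", wear_wrist = "wear_block_rule"),
    by = c("participant_id", "date", "hour")
  )
  joint <- dplyr::arrange(joint, .data$participant_id, .data$date, .data$hour)
  if (nrow(joint) == 0L) {
    return(tibble::tibble(participant_id = character(),
                          date = as.Date(character()), hour = integer(),
                          steps_hip = integer(), steps_wrist = integer(),
                          block_id = character()))
  }
  joint$both <- joint$wear_hip & joint$wear_wrist
  # runs of consecutive clock hours with joint wear, within a day:
  # a run breaks at day changes, hour gaps, or any change of joint-wear state
  n <- nrow(joint)
  day_key <- paste(joint$participant_id, joint$date, sep = "\r")
  breaks <- c(TRUE,
              day_key[-1] != day_key[-n] |
                joint$hour[-1] != joint$hour[-n] + 1L |
                joint$both[-1] != joint$both[-n])
  joint$run_id <- cumsum(breaks)
  worn <- joint[joint$both, ]
  if (nrow(worn) == 0L) return(worn_empty())
  runs <- dplyr::mutate(
    dplyr::group_by(worn, .data$run_id),
    run_len = dplyr::n(),
    pos = dplyr::row_number()
  )
  runs <- dplyr::ungroup(runs)
  interior <- runs$run_len >= min_block_h &
    runs$pos > trim_h & runs$pos <= runs$run_len - trim_h
  out <- runs[interior, ]
  tibble::tibble(
    participant_id = out$participant_id,
    date = out$date,
    hour = out$hour,
    steps_hip = out$steps_hip,
    steps_wrist = out$steps_wrist,
    block_id = paste(out$participant_id, format(out$date), out$run_id, sep = "_")
  )
}

worn_empty <- function() {
  tibble::tibble(participant_id = character(), date = as.Date(character()),
                 hour = integer(), steps_hip = integer(),
                 steps_wrist = integer(), block_id = character())
}

#' Build the trimmed overlap person-hour sample (sample 2)
#'
#' Restricts hour cells to the participant-dates of sample 1, finds trimmed
#' overlap blocks, and applies the exclusion cascade: participants with no
#' interior overlap hours (i.e. <`min_block_h` hours of overlapping wear),
#' participants residing outside the Eastern time zone (wrist timestamps
#' follow travel; hip timestamps do not), and an optional extreme-outlier
#' rule on the absolute hourly difference. Every removal is ledgered.
#'
#' @param hip_cells,wrist_cells Hour-cell tibbles.
#' @param sample1_pairs Pairs from [build_sample1()].
#' @param roster Roster tibble with `in_eastern_time`.
#' @param min_block_h,trim_h Block parameters (defaults 3 and 1).
#' @param est_filter Apply the Eastern-time exclusion (default TRUE).
#' @param outlier_max_abs_diff Hourly |wrist - hip| above this is flagged
#'   (default 10000 steps).
#' @param outlier_remove Remove flagged hours (default FALSE: flag only).
#' @return List with `pairs` (paired hours), `ledger`, and `outliers`
#'   (flagged hours).
#' @export
build_sample2 <- function(hip_cells, wrist_cells, sample1_pairs, roster,
                          min_block_h = 3L, trim_h = 1L, est_filter = TRUE,
                          outlier_max_abs_diff = 10000, outlier_remove = FALSE) {
  ledger <- ledger_new()
  keys <- dplyr::distinct(sample1_pairs, .data$participant_id, .data$date)
  hip_cells <- dplyr::semi_join(hip_cells, keys, by = c("participant_id", "date"))
  wrist_cells <- dplyr::semi_join(wrist_cells, keys, by = c("participant_id", "date"))
  hours <- find_overlap_blocks(hip_cells, wrist_cells, min_block_h, trim_h)

  s1_participants <- unique(sample1_pairs$participant_id)
  no_overlap <- setdiff(s1_participants, unique(hours$participant_id))
  ledger <- ledger_add(
    ledger, "sample2_overlap",
    sprintf("<%d h of overlapping wear in every day (no interior hours)", min_block_h),
    n_participants_removed = length(no_overlap), n_units_removed = 0L
  )

  if (isTRUE(est_filter)) {
    est <- roster$participant_id[roster$in_eastern_time]
    drop <- unique(hours$participant_id[!(hours$participant_id %in% est)])
    n_drop_units <- sum(!(hours$participant_id %in% est))
    hours <- hours[hours$participant_id %in% est, ]
    ledger <- ledger_add(ledger, "sample2_timezone",
                         "participant resides outside Eastern time",
                         n_participants_removed = length(drop),
                         n_units_removed = n_drop_units)
  }

  adiff <- abs(hours$steps_wrist - hours$steps_hip)
  flagged <- hours[adiff > outlier_max_abs_diff, ]
  if (isTRUE(outlier_remove) && nrow(flagged) > 0L) {
    before <- unique(hours$participant_id)
    hours <- hours[adiff <= outlier_max_abs_diff, ]
    ledger <- ledger_add(
      ledger, "sample2_outlier",
      sprintf("extreme person-hour |diff| > %g steps removed", outlier_max_abs_diff),
      n_participants_removed = length(setdiff(before, unique(hours$participant_id))),
      n_units_removed = nrow(flagged)
    )
  } else if (nrow(flagged) > 0L) {
    ledger <- ledger_add(
      ledger, "sample2_outlier",
      sprintf("extreme person-hour |diff| > %g steps flagged (not removed)",
              outlier_max_abs_diff),
      n_participants_removed = 0L, n_units_removed = 0L
    )
  }
  list(pairs = hours, ledger = ledger, outliers = flagged)
}

#' Classify paired days into scatterplot sections
#'
#' Partitions paired person-days into six regions of the (hip, wrist) plane
#' by two step thresholds on each axis (defaults 1000 and 30000 steps/day):
#' C is the closed central box (both devices within `[low, high]`); E holds
#' days where both devices fall outside the band on the same side; A and D
#' hold days where exactly the hip (A) or wrist (D) device exceeds `high`;
#' B and F hold days where exactly the wrist (B) or hip (F) device falls
#' below `low`. Values exactly at a threshold fall in C.
#'
#' @param pairs Paired-day tibble from [build_sample1()].
#' @param low,high Step thresholds (defaults 1000 and 30000).
#' @return List with `by_day` (pairs plus `section`) and `counts` (section,
#'   n_days, n_participants).
#' @export
classify_scatter_sections <- function(pairs, low = 1000, high = 30000) {
  h <- pairs$steps_hip
  w <- pairs$steps_wrist
  section <- rep(NA_character_, nrow(pairs))
  in_box <- h >= low & h <= high & w >= low & w <= high
  section[in_box] <- "C"
  both_out <- (h > high & w > high) | (h < low & w < low)
  section[is.na(section) & both_out] <- "E"
  section[is.na(section) & h > high] <- "A"
  section[is.na(section) & w > high] <- "D"
  section[is.na(section) & w < low] <- "B"
  section[is.na(section) & h < low] <- "F"
  pairs$section <- section
  counts <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(section = factor(section, levels = LETTERS[1:6]),
                                   participant_id = pairs$participant_id),
                    .data$section, .drop = FALSE),
    n_days = dplyr::n(),
    n_participants = dplyr::n_distinct(.data$participant_id),
    .groups = "drop"
  )
  counts$section <- as.character(counts$section)
  list(by_day = pairs, counts = counts)
}

#' Apply a sensitivity-analysis filter to paired days
#'
#' Modes: `drop_section_A_participants` removes all days of participants who
#' contributed a section-A day (hip above the high threshold);
#' `drop_outer_section_participants` removes participants with any day
#' outside the central section; `wear_diff_le_1h` removes person-days whose
#' between-device wear time differs by more than 1 hour; `watch_5_to_10h`
#' rebuilds the pairing keeping days with 5-10 h wrist wear and >=10 h hip
#' wear (requires `person_days`).
#'
#' @param pairs Paired-day tibble.
#' @param mode One of the modes above.
#' @param low,high Section thresholds (see [classify_scatter_sections()]).
#' @param person_days Person-day tibble (both devices), needed for
#'   `watch_5_to_10h`.
#' @return List with `pairs` (filtered) and `ledger`.
#' @export
apply_sensitivity_filters <- function(pairs,
                                      mode = c("drop_section_A_participants",
                                               "drop_outer_section_participants",
                                               "wear_diff_le_1h",
                                               "watch_5_to_10h"),
                                      low = 1000, high = 30000,
                                      person_days = NULL) {
  mode <- rlang::arg_match(mode)
  ledger <- ledger_new()
  if (mode %in% c("drop_section_A_participants", "drop_outer_section_participants")) {
    sec <- classify_scatter_sections(pairs, low, high)$by_day
    bad_sections <- if (mode == "drop_section_A_participants") "A" else setdiff(LETTERS[1:6], "C")
    drop <- unique(sec$participant_id[sec$section %in% bad_sections])
    out <- pairs[!(pairs$participant_id %in% drop), ]
    ledger <- ledger_add(ledger, mode,
                         sprintf("participants with any day in section(s) %s",
                                 paste(bad_sections, collapse = "")),
                         n_participants_removed = length(drop),
                         n_units_removed = nrow(pairs) - nrow(out))
  } else if (mode == "wear_diff_le_1h") {
    out <- pairs[pairs$wear_diff <= 1, ]
    ledger <- ledger_add(ledger, mode, "person-days with wear-time difference > 1 h",
                         n_participants_removed =
                           length(setdiff(unique(pairs$participant_id),
                                          unique(out$participant_id))),
                         n_units_removed = nrow(pairs) - nrow(out))
  } else { # watch_5_to_10h
    if (is.null(person_days)) {
      stop_input("mode 'watch_5_to_10h' requires the person_days table")
    }
    hip <- person_days[person_days$device == "hip" & person_days$wear_hours >= 10, ]
    wrist <- person_days[person_days$device == "wrist" &
                           person_days$wear_hours >= 5 &
                           person_days$wear_hours < 10, ]
    out <- dplyr::inner_join(
      dplyr::select(hip, "participant_id", "date",
                    steps_hip = "total_steps", wear_hours_hip = "wear_hours"),
      dplyr::select(wrist, "participant_id", "date",
                    steps_wrist = "total_steps", wear_hours_wrist = "wear_hours"),
      by = c("participant_id", "date")
    )
    out$wear_diff <- abs(out$wear_hours_wrist - out$wear_hours_hip)
    ledger <- ledger_add(ledger, mode,
                         "days re-paired: wrist worn 5-10 h, hip worn >=10 h",
                         n_participants_removed = NA_integer_,
                         n_units_removed = NA_integer_)
  }
  list(pairs = out, ledger = ledger)
}
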