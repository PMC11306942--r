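#' Pipeline configuration
#'
#' Collects every tunable of the analysis with the source protocol's values
#' as defaults: 30 s hip epochs reintegrated to 60 s for nonwear detection
#' (Choi 90/2/30), an 18 h daily possible-wear window (00:00-06:00 removed),
#' valid days of >= 10 wear hours with >= 3 valid days per participant,
#' wrist wear rules at 30 steps / 2 heart-rate samples, overlap blocks of
#' >= 3 h trimmed by 1 h at each end, the Eastern-time exclusion, tolerance
#' bands {15, 5}%, and steps/day thresholds {3000, 6000, 8000, 10000}.
#'
#' @param sim A [sim_config()] (or arguments for one) used when no input
#'   files are given.
#' @param epoch_s Hip input epoch length (seconds).
#' @param choi [choi_params()] for nonwear detection.
#' @param daily_window Hip possible-wear window `c(start_hour, end_hour)`.
#' @param min_wear_hours Valid-day wear threshold (hours).
#' @param min_valid_days Valid days required per participant.
#' @param wrist_steps_min,wrist_hr_min Wrist wear-rule thresholds.
#' @param min_block_h,trim_h Overlap-block length and trim.
#' @param est_filter Apply the Eastern-time exclusion in sample 2.
#' @param outlier_max_abs_diff,outlier_remove Extreme person-hour rule.
#' @param tolerances Percent tolerance bands.
#' @param thresholds Steps/day thresholds for kappa.
#' @param section_low,section_high Scatter-section thresholds.
#' @param seed Seed (defaults to the simulation seed).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            epoch_s = 30L,
                            choi = choi_params(),
                            daily_window = c(6L, 24L),
                            min_wear_hours = 10,
                            min_valid_days = 3L,
                            wrist_steps_min = 30L,
                            wrist_hr_min = 2L,
                            min_block_h = 3L,
                            trim_h = 1L,
                            est_filter = TRUE,
                            outlier_max_abs_diff = 10000,
                            outlier_remove = FALSE,
                            tolerances = c(15, 5),
                            thresholds = c(3000, 6000, 8000, 10000),
                            section_low = 1000,
                            section_high = 30000,
                            seed = NULL) {
  if (!inherits(sim, "sim_config")) sim <- do.call(sim_config, sim)
  structure(list(
    sim = sim, epoch_s = assert_count(epoch_s, "epoch_s"),
    choi = if (inherits(choi, "choi_params")) choi else do.call(choi_params, choi),
    daily_window = as.integer(daily_window),
    min_wear_hours = min_wear_hours,
    min_valid_days = assert_count(min_valid_days, "min_valid_days"),
    wrist_steps_min = wrist_steps_min, wrist_hr_min = wrist_hr_min,
    min_block_h = assert_count(min_block_h, "min_block_h"),
    trim_h = assert_count(trim_h, "trim_h", min = 0L),
    est_filter = isTRUE(est_filter),
    outlier_max_abs_diff = outlier_max_abs_diff,
    outlier_remove = isTRUE(outlier_remove),
    tolerances = tolerances, thresholds = thresholds,
    section_low = section_low, section_high = section_high,
    seed = if (is.null(seed)) sim$seed else assert_count(seed, "seed", min = 0L)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from a JSON file
#'
#' @param path JSON file whose keys are [pipeline_config()] arguments (with
#'   `sim` a nested object of [sim_config()] arguments).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$sim)) raw$sim <- do.call(sim_config, raw$sim)
  do.call(pipeline_config, raw)
}

#' Run the full two-device agreement pipeline
#'
#' simulate (or load) -> preprocess -> match -> analyze -> report. Hip
#' epochs are reintegrated to one minute, Choi nonwear is detected per
#' participant over the contiguous minute record, the daily window and wear
#' rules produce hour cells and person-days, valid participants are paired
#' into the same-date person-day sample (sample 1) and the trimmed
#' overlap-block person-hour sample (sample 2), and the agreement suite,
#' threshold concordance, adjusted slopes, interaction tests and subgroup
#' analyses are computed. Deterministic given the configuration seed.
#'
#' @param config A [pipeline_config()].
#' @param hip,watch,roster Optional input tibbles (from the `io` readers);
#'   when omitted, a cohort is simulated from `config$sim`.
#' @param out_dir Optional output directory; when given, writes
#'   `report.csv` (+ `.json` sidecar), `sections.csv`, and Bland-Altman
#'   plot-data tables for both samples.
#' @return An `agreement_report` list: `stats`, `ledger`, `details`,
#'   `config`, `samples` (the matched sets), `person_days`.
#' @export
run_pipeline <- function(config = pipeline_config(), hip = NULL, watch = NULL,
                         roster = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(hip) || is.null(watch) || is.null(roster)) {
    cohort <- simulate_cohort(config$sim)
    hip <- cohort$hip; watch <- cohort$watch; roster <- cohort$roster
  }
  ledger <- ledger_new()

  # ---- preprocessing -----------------------------------------------------
  minutes <- hip_minute_grid(hip, epoch_s = config$epoch_s)
  minutes <- dplyr::ungroup(dplyr::mutate(
    dplyr::group_by(minutes, .data$participant_id),
    wear = detect_nonwear_choi(.data$activity_count, config$choi)
  ))
  minutes <- apply_daily_window(minutes, config$daily_window)
  hip_cells <- hip_hour_cells(minutes)
  wrist_cells <- wrist_hour_cells(watch, config$wrist_steps_min,
                                  config$wrist_hr_min)
  person_days <- dplyr::bind_rows(
    summarize_person_days(hip_cells, config$min_wear_hours),
    summarize_person_days(wrist_cells, config$min_wear_hours)
  )
  flt <- filter_valid_participants(person_days, config$min_valid_days)
  ledger <- dplyr::bind_rows(ledger, flt$ledger)

  # ---- matching ----------------------------------------------------------
  s1 <- build_sample1(
    flt$person_days[flt$person_days$device == "hip", ],
    flt$person_days[flt$person_days$device == "wrist", ]
  )
  ledger <- dplyr::bind_rows(ledger, s1$ledger)
  sections <- classify_scatter_sections(s1$pairs, config$section_low,
                                        config$section_high)
  s2 <- build_sample2(hip_cells, wrist_cells, s1$pairs, roster,
                      min_block_h = config$min_block_h, trim_h = config$trim_h,
                      est_filter = config$est_filter,
                      outlier_max_abs_diff = config$outlier_max_abs_diff,
                      outlier_remove = config$outlier_remove)
  ledger <- dplyr::bind_rows(ledger, s2$ledger)

  # ---- statistics --------------------------------------------------------
  out <- analyze_samples(s1$pairs, s2$pairs, roster, config)
  stats_tbl <- out$stats
  details <- out$details
  details$sections <- sections$counts
  details$outliers_flagged <- nrow(s2$outliers)

  report <- structure(list(
    stats = stats_tbl, ledger = ledger, details = details,
    config = report_config(config),
    samples = list(sample1 = s1$pairs, sample2 = s2$pairs,
                   sections = sections$by_day),
    person_days = flt$person_days
  ), class = "agreement_report")

  if (!is.null(out_dir)) write_pipeline_outputs(report, out_dir)
  report
}

analyze_samples <- function(pairs1, pairs2, roster, config) {
  details <- list()
  stats_list <- list()

  if (nrow(pairs1) > 0) {
    a1 <- agreement_suite(pairs1$steps_wrist, pairs1$steps_hip,
                          pairs1$participant_id, sample = "sample1",
                          tolerances = config$tolerances)
    stats_list$s1 <- a1$stats
    details$sample1 <- a1$details

    avg <- dplyr::summarise(
      dplyr::group_by(pairs1, .data$participant_id),
      avg_hip = mean(.data$steps_hip), avg_wrist = mean(.data$steps_wrist),
      .groups = "drop"
    )
    thr <- threshold_concordance(avg$avg_wrist, avg$avg_hip, config$thresholds)
    details$threshold_contingency <- setNames(thr$contingency,
                                              paste0("T", thr$threshold))
    thr_rows <- dplyr::bind_rows(
      tibble::tibble(sample = "sample1", subgroup = "all",
                     statistic = sprintf("kappa_%g", thr$threshold),
                     estimate = thr$kappa, ci_low = thr$ci_low,
                     ci_high = thr$ci_high,
                     n_participants = nrow(avg), n_units = thr$n),
      tibble::tibble(sample = "sample1", subgroup = "all",
                     statistic = sprintf("pct_concordant_%g", thr$threshold),
                     estimate = thr$pct_concordant,
                     ci_low = NA_real_, ci_high = NA_real_,
                     n_participants = nrow(avg), n_units = thr$n)
    )
    thr_day <- threshold_concordance(pairs1$steps_wrist, pairs1$steps_hip,
                                     config$thresholds)
    thr_day_rows <- tibble::tibble(
      sample = "sample1", subgroup = "per_person_day",
      statistic = sprintf("kappa_%g", thr_day$threshold),
      estimate = thr_day$kappa, ci_low = thr_day$ci_low,
      ci_high = thr_day$ci_high,
      n_participants = length(unique(pairs1$participant_id)),
      n_units = thr_day$n
    )
    stats_list$thr <- dplyr::bind_rows(thr_rows, thr_day_rows)

    # degenerate worlds (e.g. a constant wear-time difference in noise-free
    # simulations) make these models rank deficient; skip with a note
    sl1 <- tryCatch(adjusted_slope(pairs1, roster, include_wear_diff = TRUE),
                    error = function(e) conditionMessage(e))
    if (is.list(sl1)) {
      stats_list$sl1 <- tibble::tibble(
        sample = "sample1", subgroup = "all", statistic = "adjusted_slope",
        estimate = sl1$beta, ci_low = sl1$ci_low, ci_high = sl1$ci_high,
        n_participants = sl1$n_participants, n_units = sl1$n
      )
    } else details$adjusted_slope_skipped <- sl1
    long1 <- pairs_to_long(pairs1, roster)
    it <- tryCatch(interaction_test(long1, "wear_time"),
                   error = function(e) conditionMessage(e))
    if (is.list(it)) {
      details$interaction_wear_time <- it
      stats_list$it1 <- tibble::tibble(
        sample = "sample1", subgroup = "all",
        statistic = "interaction_wear_time_p",
        estimate = it$p_value, ci_low = NA_real_, ci_high = NA_real_,
        n_participants = length(unique(pairs1$participant_id)),
        n_units = nrow(pairs1)
      )
    } else details$interaction_wear_time_skipped <- it
  }

  if (nrow(pairs2) > 0) {
    a2 <- agreement_suite(pairs2$steps_wrist, pairs2$steps_hip,
                          pairs2$participant_id, sample = "sample2",
                          tolerances = config$tolerances)
    stats_list$s2 <- a2$stats
    details$sample2 <- a2$details
    sg <- subgroup_agreement(pairs2, roster, sample = "sample2",
                             tolerances = config$tolerances)
    stats_list$sg <- sg$stats
    details$sample2_subgroups <- sg$details
  }
  list(stats = dplyr::bind_rows(stats_list), details = details)
}

# two rows per paired day (one per device) for interaction models
pairs_to_long <- function(pairs, roster) {
  long <- dplyr::bind_rows(
    tibble::tibble(participant_id = pairs$participant_id, date = pairs$date,
                   device = "hip", steps = pairs$steps_hip,
                   wear_time = pairs$wear_hours_hip),
    tibble::tibble(participant_id = pairs$participant_id, date = pairs$date,
                   device = "wrist", steps = pairs$steps_wrist,
                   wear_time = pairs$wear_hours_wrist)
  )
  dplyr::inner_join(long, roster, by = "participant_id")
}

report_config <- function(config) {
  cfg <- unclass(config)
  cfg$sim <- unclass(cfg$sim)
  cfg$sim$start_date <- format(cfg$sim$start_date)
  cfg$choi <- unclass(cfg$choi)
  cfg
}

write_pipeline_outputs <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_report(report, file.path(out_dir, "report.csv"))
  readr::write_csv(report$details$sections, file.path(out_dir, "sections.csv"),
                   progress = FALSE)
  for (s in c("sample1", "sample2")) {
    pr <- report$samples[[s]]
    if (is.null(pr) || nrow(pr) == 0) next
    ba <- tibble::tibble(
      participant_id = pr$participant_id,
      unit_mean = (pr$steps_wrist + pr$steps_hip) / 2,
      difference = pr$steps_wrist - pr$steps_hip,
      pct_difference = percent_difference(pr$steps_wrist, pr$steps_hip)
    )
    readr::write_csv(ba, file.path(out_dir, paste0("ba_data_", s, ".csv")),
                     progress = FALSE)
  }
  invisible(out_dir)
}

#' Re-run the agreement analysis under each sensitivity filter
#'
#' Applies every [apply_sensitivity_filters()] mode to the base sample-1
#' pairs (rebuilding pairs from person-days for the 5-10 h wrist mode) and
#' recomputes the agreement suite for each, including the stricter 5%
#' tolerance band.
#'
#' @param report Base `agreement_report` from [run_pipeline()].
#' @param config The [pipeline_config()] used for the base run.
#' @return Named list of reports (stats + ledger), one per mode.
#' @export
run_sensitivity_battery <- function(report, config = pipeline_config()) {
  pairs <- report$samples$sample1
  modes <- c("drop_section_A_participants", "drop_outer_section_participants",
             "wear_diff_le_1h", "watch_5_to_10h")
  out <- list()
  for (mode in modes) {
    f <- apply_sensitivity_filters(pairs, mode,
                                   low = config$section_low,
                                   high = config$section_high,
                                   person_days = report$person_days)
    if (nrow(f$pairs) < 2 || length(unique(f$pairs$participant_id)) < 2) {
      out[[mode]] <- list(stats = NULL, ledger = f$ledger)
      next
    }
    a <- agreement_suite(f$pairs$steps_wrist, f$pairs$steps_hip,
                         f$pairs$participant_id,
                         sample = paste0("sample1_", mode),
                         tolerances = union(config$tolerances, 5))
    out[[mode]] <- list(stats = a$stats, ledger = f$ledger, pairs = f$pairs)
  }
  out
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Two-device step-count agreement report\n")
  s1 <- x$samples$sample1; s2 <- x$samples$sample2
  cat(sprintf("  sample 1: %d participants, %d person-days\n",
              length(unique(s1$participant_id)), nrow(s1)))
  cat(sprintf("  sample 2: %d participants, %d person-hours\n",
              length(unique(s2$participant_id)), nrow(s2)))
  print(as.data.frame(x$stats), digits = 3)
  invisible(x)
}
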