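pd_row <- function(id, date, device, wear, steps) {
  tibble::tibble(participant_id = id, date = as.Date(date), device = device,
                 wear_hours = wear, total_steps = steps,
                 is_valid = wear >= 10)
}

test_that("sample 1 pairs only same-date days valid on both devices", {
  hip <- dplyr::bind_rows(
    pd_row("A", "2017-04-02", "hip", 12, 8000),
    pd_row("A", "2017-04-03", "hip", 12, 9000),
    pd_row("B", "2017-04-02", "hip", 12, 7000)
  )
  wrist <- dplyr::bind_rows(
    pd_row("A", "2017-04-04", "wrist", 12, 8100),   # disjoint date
    pd_row("B", "2017-04-02", "wrist", 11, 6900),
    pd_row("B", "2017-04-03", "wrist", 9, 6000)     # invalid day
  )
  s1 <- build_sample1(hip, wrist)
  expect_equal(nrow(s1$pairs), 1L)
  expect_equal(s1$pairs$participant_id, "B")
  expect_equal(s1$pairs$wear_diff, 1)
  # A had valid days on both devices but no shared date
  expect_false("A" %in% s1$pairs$participant_id)
})

test_that("five overlapping valid dates give five paired days", {
  dates <- as.Date("2017-04-02") + 0:4
  hip <- pd_row("A", dates, "hip", 12, 8000)
  wrist <- pd_row("A", dates, "wrist", 14, 8200)
  s1 <- build_sample1(hip, wrist)
  expect_equal(nrow(s1$pairs), 5L)
  expect_true(all(s1$pairs$wear_diff == 2))
})

test_that("an engineered 20-participant cohort pairs exactly as enumerated", {
  withr::local_seed(99)
  base <- as.Date("2017-04-02")
  hip_list <- list(); wrist_list <- list(); expected <- 0L
  for (i in 1:20) {
    id <- sprintf("P%02d", i)
    hip_dates <- base + 0:6
    wrist_dates <- base + sample(0:6, sample(3:7, 1))
    hip_valid <- sample(c(TRUE, FALSE), 7, replace = TRUE, prob = c(.8, .2))
    wrist_valid <- rep(TRUE, length(wrist_dates))
    hip_list[[i]] <- pd_row(id, hip_dates, "hip",
                            ifelse(hip_valid, 12, 8), 8000)
    wrist_list[[i]] <- pd_row(id, wrist_dates, "wrist", 14, 8200)
    expected <- expected + length(intersect(hip_dates[hip_valid], wrist_dates))
  }
  s1 <- build_sample1(dplyr::bind_rows(hip_list), dplyr::bind_rows(wrist_list))
  expect_equal(nrow(s1$pairs), expected)
})

test_that("overlap blocks trim endpoints and need three consecutive hours", {
  # both worn 08:00-19:00 (12 h) -> 10 interior hours
  hip <- make_hip_cells("A", "2017-04-02", 0:23,
                        c(rep(0L, 8), rep(400L, 12), rep(0L, 4)))
  wrist <- make_wrist_cells("A", "2017-04-02", 0:23,
                            c(rep(0L, 8), rep(380L, 12), rep(0L, 4)), hr = 0L)
  ph <- find_overlap_blocks(hip, wrist)
  expect_equal(nrow(ph), 10L)
  expect_equal(ph$hour, 9:18)

  # exactly 3 consecutive hours -> 1 interior hour
  hip3 <- make_hip_cells("A", "2017-04-02", 10:12, rep(300L, 3))
  wrist3 <- make_wrist_cells("A", "2017-04-02", 10:12, rep(280L, 3), hr = 5L)
  ph3 <- find_overlap_blocks(hip3, wrist3)
  expect_equal(ph3$hour, 11L)

  # alternating hour-on/hour-off: no run of 3, nothing survives
  hrs <- 0:23
  alt <- ifelse(hrs %% 2 == 0, 400L, 0L)
  hip_a <- make_hip_cells("A", "2017-04-02", hrs, alt)
  wrist_a <- make_wrist_cells("A", "2017-04-02", hrs, alt, hr = 0L)
  expect_equal(nrow(find_overlap_blocks(hip_a, wrist_a)), 0L)
})

test_that("a missing wrist hour splits an overlap block", {
  hip <- make_hip_cells("A", "2017-04-02", 6:17, rep(400L, 12))
  steps <- rep(380L, 12); steps[6] <- NA   # hour 11 missing
  wrist <- make_wrist_cells("A", "2017-04-02", 6:17, steps, hr = 5L)
  ph <- find_overlap_blocks(hip, wrist)
  # blocks 06-10 (5 h -> 3 interior) and 12-17 (6 h -> 4 interior)
  expect_equal(ph$hour, c(7:9, 13:16))
  expect_equal(length(unique(ph$block_id)), 2L)
})

test_that("sample 2 applies the overlap, timezone and outlier cascade", {
  base <- as.Date("2017-04-02")
  # A: 12 h joint wear; B: only 2 h joint wear; C: good data, non-Eastern
  hip <- dplyr::bind_rows(
    make_hip_cells("A", base, 6:17, rep(400L, 12)),
    make_hip_cells("B", base, c(6, 7, 12, 13), rep(400L, 4)),
    make_hip_cells("C", base, 6:17, rep(400L, 12))
  )
  wrist <- dplyr::bind_rows(
    make_wrist_cells("A", base, 6:17, rep(380L, 12)),
    make_wrist_cells("B", base, c(6, 7, 12, 13), rep(380L, 4)),
    make_wrist_cells("C", base, 6:17, rep(380L, 12))
  )
  s1_pairs <- tibble::tibble(
    participant_id = c("A", "B", "C"), date = base,
    steps_hip = 4800, steps_wrist = 4560,
    wear_hours_hip = 12, wear_hours_wrist = 12, wear_diff = 0
  )
  roster <- make_roster(c("A", "B", "C"), eastern = c(TRUE, TRUE, FALSE))
  s2 <- build_sample2(hip, wrist, s1_pairs, roster)
  expect_setequal(unique(s2$pairs$participant_id), "A")
  lg <- s2$ledger
  expect_equal(lg$n_participants_removed[lg$stage == "sample2_overlap"], 1L)
  expect_equal(lg$n_participants_removed[lg$stage == "sample2_timezone"], 1L)

  # outlier: flagged by default, removed only on request
  wrist_out <- wrist
  wrist_out$steps[wrist_out$participant_id == "A" & wrist_out$hour == 10] <- 30000L
  cells_out <- wrist_hour_cells(make_watch_rows("A", base, 6:17,
                                                {s <- rep(380L, 12); s[5] <- 30000L; s},
                                                rep(5L, 12)))
  s2f <- build_sample2(hip, cells_out, s1_pairs[1, ], roster[1, ])
  expect_equal(nrow(s2f$outliers), 1L)
  expect_true(any(s2f$pairs$steps_wrist == 30000L))
  s2r <- build_sample2(hip, cells_out, s1_pairs[1, ], roster[1, ],
                       outlier_remove = TRUE)
  expect_false(any(s2r$pairs$steps_wrist == 30000L))
  expect_equal(s2r$ledger$n_units_removed[s2r$ledger$stage == "sample2_outlier"], 1L)
})

test_that("scatter sections partition all days with ties in the central box", {
  pairs <- tibble::tibble(
    participant_id = sprintf("P%d", 1:7),
    date = as.Date("2017-04-02"),
    steps_hip = c(7000, 35000, 5000, 500, 900, 1000, 40000),
    steps_wrist = c(7000, 5000, 35000, 5000, 700, 30000, 45000),
    wear_hours_hip = 12, wear_hours_wrist = 12, wear_diff = 0
  )
  cs <- classify_scatter_sections(pairs)
  expect_equal(cs$by_day$section,
               c("C",  # central
                 "A",  # hip above 30000
                 "D",  # wrist above 30000
                 "F",  # hip below 1000, wrist inside
                 "E",  # both below 1000
                 "C",  # both exactly at thresholds: closed box
                 "E")) # both above 30000
  expect_equal(sum(cs$counts$n_days), nrow(pairs))

  withr::local_seed(31)
  rnd <- tibble::tibble(
    participant_id = sample(sprintf("P%d", 1:40), 300, replace = TRUE),
    date = as.Date("2017-04-02") + sample(0:9, 300, replace = TRUE),
    steps_hip = round(stats::rlnorm(300, log(7000), 1.2)),
    steps_wrist = round(stats::rlnorm(300, log(7000), 1.2)),
    wear_hours_hip = 12, wear_hours_wrist = 12, wear_diff = 0
  )
  cr <- classify_scatter_sections(rnd)
  expect_false(any(is.na(cr$by_day$section)))
  expect_equal(sum(cr$counts$n_days), 300L)
})

test_that("sensitivity filters remove what they claim and nothing else", {
  pairs <- tibble::tibble(
    participant_id = c("A", "A", "B", "C"),
    date = as.Date("2017-04-02") + c(0, 1, 0, 0),
    steps_hip = c(7000, 35000, 8000, 9000),
    steps_wrist = c(7100, 6000, 8200, 9100),
    wear_hours_hip = c(12, 12, 12, 12),
    wear_hours_wrist = c(12.5, 12, 13.5, 12),
    wear_diff = c(0.5, 0, 1.5, 0)
  )
  fA <- apply_sensitivity_filters(pairs, "drop_section_A_participants")
  expect_setequal(unique(fA$pairs$participant_id), c("B", "C"))
  expect_equal(fA$ledger$n_units_removed, 2L)

  fw <- apply_sensitivity_filters(pairs, "wear_diff_le_1h")
  expect_equal(nrow(fw$pairs), 3L)
  expect_false("B" %in% fw$pairs$participant_id)

  all_c <- pairs[c(1, 3, 4), ]
  fo <- apply_sensitivity_filters(all_c, "drop_outer_section_participants")
  expect_equal(fo$pairs, all_c)

  expect_error(apply_sensitivity_filters(pairs, "no_such_mode"))
  expect_error(apply_sensitivity_filters(pairs, "watch_5_to_10h"),
               "person_days")

  pdays <- dplyr::bind_rows(
    pd_row("A", "2017-04-02", "hip", 12, 8000),
    pd_row("A", "2017-04-02", "wrist", 7, 5200),
    pd_row("B", "2017-04-02", "hip", 12, 9000),
    pd_row("B", "2017-04-02", "wrist", 11, 8800)
  )
  f5 <- apply_sensitivity_filters(pairs, "watch_5_to_10h", person_days = pdays)
  expect_equal(f5$pairs$participant_id, "A")
  expect_equal(f5$pairs$steps_wrist, 5200)
})
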