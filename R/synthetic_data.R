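#' Configuration for the synthetic paired-device cohort
#'
#' Describes a free-living cohort wearing a hip epoch-recording accelerometer
#' and a wrist device reporting hourly step totals. True hourly steps are
#' negative-binomial around `personal_level x hourly_activity_profile[h]`,
#' with a log-normal personal activity level; each device observes the truth
#' through independent multiplicative log-normal noise; the wrist device
#' applies a step ratio (`device_ratio`), is removed nightly for charging,
#' and suffers connectivity interruptions (missing step counts with heart
#' rate still recorded) in geometric-length runs; the hip device is removed
#' for sleep and in daytime removal bouts.
#'
#' Defaults emulate the cohort the analysis targets: a flat waking profile of
#' 450 steps/h over 06:00-22:00 (about 7200 steps/day, matching a median
#' near 7000), hip wear around 14 h/day under the 18 h window and wrist wear
#' around 16 h/day. Hip removal bouts are hour-aligned (whole clock hours)
#' so that matched interior hours stay analytically tractable.
#'
#' @param n_participants,n_days Cohort size and days per participant.
#' @param seed Integer seed; fixed seed gives bit-reproducible output.
#' @param hourly_activity_profile 24 expected step rates (steps/hour) by hour
#'   of day.
#' @param between_participant_sd Log-scale SD of the personal activity level.
#' @param nb_size Negative-binomial dispersion (size) of true hourly steps.
#' @param device_ratio Expected wrist/hip step ratio (true hourly scale).
#' @param hip_noise_cv,watch_noise_cv Coefficients of variation of the
#'   per-hour multiplicative device noise.
#' @param hip_nonwear_daily List with `bouts_per_day` (Poisson mean) and
#'   `mean_duration_min` (>= 60; rounded to whole hours).
#' @param watch_charge_window,sleep_window Length-2 `c(start_hour, end_hour)`
#'   clock windows (may wrap midnight) for nightly wrist charging and for
#'   sleep (hip off-body, ~zero true steps).
#' @param interruption_prob Marginal per-hour probability that a worn wrist
#'   hour has missing steps while heart rate persists.
#' @param interruption_run_mean Mean run length (hours) of interruptions.
#' @param watch_offwrist_mean Mean (Poisson) extra off-wrist hours per day
#'   appended after the charge window (late watch donning), giving realistic
#'   day-to-day variation in wrist wear time; 0 disables.
#' @param device_ratio_obese,watch_noise_cv_obese Optional overrides applied
#'   to participants with obesity (for engineered-effect experiments).
#' @param roster_params Means/proportions for the simulated covariate roster.
#' @param start_date First calendar date of wear.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_participants = 100L,
                       n_days = 8L,
                       seed = 1L,
                       hourly_activity_profile = default_activity_profile(),
                       between_participant_sd = 0.5,
                       nb_size = 8,
                       device_ratio = 0.95,
                       hip_noise_cv = 0.3,
                       watch_noise_cv = 0.45,
                       hip_nonwear_daily = list(bouts_per_day = 1.5,
                                                mean_duration_min = 90),
                       watch_charge_window = c(22L, 6L),
                       sleep_window = c(22L, 6L),
                       interruption_prob = 0.08,
                       interruption_run_mean = 3,
                       watch_offwrist_mean = 1,
                       device_ratio_obese = NULL,
                       watch_noise_cv_obese = NULL,
                       roster_params = list(mean_age = 51.7, sd_age = 8.9,
                                            prop_female = 0.57,
                                            prop_mobility = 0.163,
                                            prop_non_eastern = 0.07,
                                            mean_height = 66.8, sd_height = 3.6,
                                            mean_bmi = 28.2, sd_bmi = 5.7),
                       start_date = "2017-04-02") {
  cfg <- list(
    n_participants = assert_count(n_participants, "n_participants"),
    n_days = assert_count(n_days, "n_days"),
    seed = assert_count(seed, "seed", min = 0L),
    hourly_activity_profile = hourly_activity_profile,
    between_participant_sd = between_participant_sd,
    nb_size = nb_size,
    device_ratio = device_ratio,
    hip_noise_cv = hip_noise_cv,
    watch_noise_cv = watch_noise_cv,
    hip_nonwear_daily = hip_nonwear_daily,
    watch_charge_window = as.integer(watch_charge_window),
    sleep_window = as.integer(sleep_window),
    interruption_prob = interruption_prob,
    interruption_run_mean = interruption_run_mean,
    watch_offwrist_mean = watch_offwrist_mean,
    device_ratio_obese = device_ratio_obese,
    watch_noise_cv_obese = watch_noise_cv_obese,
    roster_params = roster_params,
    start_date = as.Date(start_date)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @export
default_activity_profile <- function() {
  prof <- rep(0, 24)
  prof[7:22] <- 450   # hours 6..21 inclusive
  prof
}

validate_sim_config <- function(cfg) {
  p <- cfg$hourly_activity_profile
  if (length(p) != 24L || any(is.na(p) | p < 0)) {
    stop_input("hourly_activity_profile must be 24 non-negative rates")
  }
  if (cfg$between_participant_sd < 0) stop_input("between_participant_sd must be >= 0")
  if (cfg$nb_size <= 0) stop_input("nb_size must be > 0")
  if (cfg$device_ratio <= 0) stop_input("device_ratio must be > 0")
  if (cfg$hip_noise_cv < 0 || cfg$watch_noise_cv < 0) {
    stop_input("noise CVs must be >= 0")
  }
  if (cfg$interruption_prob < 0 || cfg$interruption_prob > 1) {
    stop_input("interruption_prob must be in [0, 1]")
  }
  if (cfg$interruption_run_mean < 1) stop_input("interruption_run_mean must be >= 1")
  if (cfg$watch_offwrist_mean < 0) stop_input("watch_offwrist_mean must be >= 0")
  b <- cfg$hip_nonwear_daily
  if (b$bouts_per_day < 0 || (b$bouts_per_day > 0 && b$mean_duration_min < 60)) {
    stop_input("hip_nonwear_daily needs bouts_per_day >= 0 and mean_duration_min >= 60")
  }
  invisible(cfg)
}

window_hours <- function(w) {
  if (w[1] == w[2]) return(integer(0))
  if (w[1] < w[2]) w[1]:(w[2] - 1L) else c(w[1]:23L, 0L:(w[2] - 1L))
}

lnorm_pars <- function(cv) {
  s2 <- log(1 + cv^2)
  c(meanlog = -s2 / 2, sdlog = sqrt(s2))   # mean 1, variance cv^2
}

#' Simulate a paired-device cohort with known ground truth
#'
#' Generates the hip 30-second epoch stream, the wrist hourly stream, a
#' covariate roster and the hour-level ground truth, all reproducible from
#' the seed. Hip epoch steps distribute each worn hour's observed total over
#' that hour's 120 epochs (epochs are zero during sleep and removal bouts);
#' wrist hourly steps are `round(true x device_ratio x noise)`, missing
#' during connectivity interruptions and absent during nightly charging;
#' heart-rate sample counts are at least 2 whenever the watch is worn.
#'
#' @param config A [sim_config()].
#' @return A `sim_cohort` list: `hip` (epoch tibble, 30 s), `watch` (hourly
#'   tibble), `roster`, `truth` (per participant-hour), `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n <- cfg$n_participants
  nd <- cfg$n_days
  ids <- sprintf("P%04d", seq_len(n))
  rp <- cfg$roster_params

  roster <- tibble::tibble(
    participant_id = ids,
    age = round(pmin(85, pmax(25, stats::rnorm(n, rp$mean_age, rp$sd_age))), 1),
    sex = ifelse(stats::runif(n) < rp$prop_female, "female", "male"),
    cohort = sample(c("gen3", "omni2", "nos"), n, replace = TRUE,
                    prob = c(0.88, 0.09, 0.03)),
    height = round(stats::rnorm(n, rp$mean_height, rp$sd_height), 1),
    bmi = round(pmax(16, stats::rnorm(n, rp$mean_bmi, rp$sd_bmi)), 1),
    mobility_limitation = stats::runif(n) < rp$prop_mobility,
    in_eastern_time = stats::runif(n) >= rp$prop_non_eastern
  )
  roster$obesity <- roster$bmi >= 30

  sigma <- cfg$between_participant_sd
  p_level <- exp(stats::rnorm(n, -sigma^2 / 2, sigma))

  ratio_i <- rep(cfg$device_ratio, n)
  wcv_i <- rep(cfg$watch_noise_cv, n)
  if (!is.null(cfg$device_ratio_obese)) ratio_i[roster$obesity] <- cfg$device_ratio_obese
  if (!is.null(cfg$watch_noise_cv_obese)) wcv_i[roster$obesity] <- cfg$watch_noise_cv_obese

  grid <- tidyr::expand_grid(pidx = seq_len(n), day = seq_len(nd) - 1L,
                             hour = 0:23)
  grid <- dplyr::arrange(grid, .data$pidx, .data$day, .data$hour)
  N <- nrow(grid)
  lambda <- p_level[grid$pidx] * cfg$hourly_activity_profile[grid$hour + 1L]
  true_steps <- stats::rnbinom(N, size = cfg$nb_size, mu = lambda)
  true_steps[lambda == 0] <- 0L

  sleep_h <- window_hours(cfg$sleep_window)
  charge_h <- window_hours(cfg$watch_charge_window)
  waking_h <- setdiff(0:23, sleep_h)

  # hip removal bouts: hour-aligned, Poisson count per day, geometric whole-
  # hour durations with mean mean_duration_min/60
  hip_off_bout <- rep(FALSE, N)
  bpd <- cfg$hip_nonwear_daily$bouts_per_day
  if (bpd > 0 && length(waking_h) > 0) {
    mean_dur_h <- cfg$hip_nonwear_daily$mean_duration_min / 60
    nb_bouts <- stats::rpois(n * nd, bpd)
    day_of <- rep(rep(seq_len(nd) - 1L, n), times = 1)
    pid_of <- rep(seq_len(n), each = nd)
    for (i in which(nb_bouts > 0)) {
      for (b in seq_len(nb_bouts[i])) {
        start <- sample(waking_h, 1L)
        dur <- 1L + stats::rgeom(1L, prob = min(1, 1 / mean_dur_h))
        hrs <- intersect(start:(start + dur - 1L), waking_h)
        rows <- (pid_of[i] - 1L) * nd * 24L + day_of[i] * 24L + hrs + 1L
        hip_off_bout[rows] <- TRUE
      }
    }
  }
  hip_worn <- !(grid$hour %in% sleep_h) & !hip_off_bout
  watch_worn <- !(grid$hour %in% charge_h)

  # late watch donning: a Poisson number of extra off-wrist hours per day,
  # appended after the charge window, so wrist wear time varies day to day
  if (cfg$watch_offwrist_mean > 0 && length(charge_h) > 0) {
    don_hour <- pmin(24L, cfg$watch_charge_window[2] +
                       stats::rpois(n * nd, cfg$watch_offwrist_mean))
    first_worn <- cfg$watch_charge_window[2]
    day_index <- (grid$pidx - 1L) * nd + grid$day + 1L
    late <- grid$hour >= first_worn & grid$hour < don_hour[day_index]
    watch_worn <- watch_worn & !late
  }

  # connectivity interruptions: geometric-length runs over each
  # participant's consecutive hour index (marginal rate ~ interruption_prob)
  interrupted <- rep(FALSE, N)
  if (cfg$interruption_prob > 0) {
    q <- cfg$interruption_prob / cfg$interruption_run_mean
    starts <- which(stats::runif(N) < q)
    if (length(starts) > 0) {
      lens <- 1L + stats::rgeom(length(starts),
                                prob = min(1, 1 / cfg$interruption_run_mean))
      part_of <- (starts - 1L) %/% (nd * 24L)
      for (j in seq_along(starts)) {
        idx <- starts[j]:min(starts[j] + lens[j] - 1L,
                             (part_of[j] + 1L) * nd * 24L)
        interrupted[idx] <- TRUE
      }
    }
  }

  hp <- lnorm_pars(cfg$hip_noise_cv)
  e_h <- stats::rlnorm(N, hp["meanlog"], hp["sdlog"])
  s_w2 <- log(1 + wcv_i[grid$pidx]^2)
  e_w <- stats::rlnorm(N, -s_w2 / 2, sqrt(s_w2))

  hip_obs <- ifelse(hip_worn, as.integer(round(true_steps * e_h)), 0L)
  watch_obs <- as.integer(round(true_steps * ratio_i[grid$pidx] * e_w))
  watch_steps <- ifelse(interrupted, NA_integer_, watch_obs)

  dates <- cfg$start_date + grid$day
  truth <- tibble::tibble(
    participant_id = ids[grid$pidx], date = dates, hour = grid$hour,
    true_steps = as.integer(true_steps),
    hip_worn = hip_worn, watch_worn = watch_worn,
    watch_interrupted = interrupted & watch_worn,
    hip_observed = hip_obs,
    watch_observed = ifelse(watch_worn, watch_steps, NA_integer_)
  )

  watch <- tibble::tibble(
    participant_id = ids[grid$pidx][watch_worn],
    date = dates[watch_worn],
    hour = grid$hour[watch_worn],
    step_count = watch_steps[watch_worn],
    hr_sample_count = 2L + stats::rpois(sum(watch_worn), 10)
  )

  hip <- build_hip_epochs(cfg, grid, dates, hip_obs, hip_worn, ids)

  structure(list(hip = hip, watch = watch, roster = roster, truth = truth,
                 config = cfg),
            class = "sim_cohort")
}

# distribute hourly totals over 120 x 30s epochs; worn epochs carry a
# baseline activity count so zero-step worn time is still visibly worn
build_hip_epochs <- function(cfg, grid, dates, hip_obs, hip_worn, ids) {
  N <- nrow(grid)
  steps_mat <- matrix(0L, nrow = 120L, ncol = N)
  worn_pos <- which(hip_worn & hip_obs > 0)
  for (i in worn_pos) {
    steps_mat[, i] <- tabulate(sample.int(120L, hip_obs[i], replace = TRUE), 120L)
  }
  n_worn <- sum(hip_worn)
  activity <- matrix(0L, nrow = 120L, ncol = N)
  activity[, hip_worn] <- steps_mat[, hip_worn] * 5L +
    matrix(stats::rpois(120L * n_worn, 15), nrow = 120L)

  epoch_offset <- (seq_len(120L) - 1L) * 30L
  base_time <- as.numeric(as.POSIXct(dates, tz = "UTC")) + grid$hour * 3600
  timestamp <- as.POSIXct(rep(base_time, each = 120L) + rep(epoch_offset, N),
                          origin = "1970-01-01", tz = "UTC")
  out <- tibble::tibble(
    participant_id = rep(ids[grid$pidx], each = 120L),
    timestamp = timestamp,
    activity_count = as.integer(activity),
    step_count = as.integer(steps_mat)
  )
  attr(out, "epoch_s") <- 30L
  out
}

#' Write a simulated cohort to the package's CSV dialects
#'
#' @param cohort A `sim_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named paths of the three files, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(hip = file.path(dir, "hip_epochs.csv"),
             watch = file.path(dir, "watch_hours.csv"),
             roster = file.path(dir, "roster.csv"))
  write_hip_epochs(cohort$hip, paths["hip"])
  write_watch_hours(cohort$watch, paths["watch"])
  write_roster(cohort$roster, paths["roster"])
  invisible(paths)
}

#' Analytic expected agreement implied by a simulation configuration
#'
#' Under the multiplicative noise model the symmetric percent difference of
#' a matched hour, `200 (r e_w - e_h) / (r e_w + e_h)`, does not involve the
#' true step count, so its mean and SD are obtained exactly (to quadrature
#' error) by integrating over the two log-normal noise terms. The absolute
#' hourly difference `D = T (r e_w - e_h)` has exact moments given the
#' negative-binomial/log-normal moments of true steps `T`:
#' `E D = E[T] (r - 1)` and
#' `Var D = E[T^2] (r^2 cv_w^2 + cv_h^2 + (r-1)^2) - (E[T])^2 (r-1)^2`.
#' With the (default) flat waking profile these are independent of which
#' waking hours survive block trimming. Used as the parameter-recovery
#' oracle for the end-to-end pipeline.
#'
#' @param config A [sim_config()].
#' @param grid_n Quadrature grid size per dimension (default 600).
#' @return List: mean_pct_diff, sd_pct_diff, mean_hourly_diff,
#'   sd_hourly_diff, e_true, e_true2 (per matched waking hour).
#' @export
expected_agreement <- function(config, grid_n = 600L) {
  cfg <- if (inherits(config, "sim_config")) config else do.call(sim_config, config)
  r <- cfg$device_ratio
  cw <- cfg$watch_noise_cv
  ch <- cfg$hip_noise_cv

  if (cw == 0 && ch == 0) {
    mean_pct <- 200 * (r - 1) / (r + 1)
    sd_pct <- 0
  } else {
    pw <- lnorm_pars(cw); ph <- lnorm_pars(ch)
    z <- stats::qnorm((seq_len(grid_n) - 0.5) / grid_n)
    ew <- exp(pw["meanlog"] + pw["sdlog"] * z)
    eh <- exp(ph["meanlog"] + ph["sdlog"] * z)
    P <- outer(ew, eh, function(a, b) 200 * (r * a - b) / (r * a + b))
    mean_pct <- mean(P)
    sd_pct <- sqrt(mean(P^2) - mean_pct^2)
  }

  sleep_h <- window_hours(cfg$sleep_window)
  charge_h <- window_hours(cfg$watch_charge_window)
  lam <- cfg$hourly_activity_profile
  hrs <- setdiff(which(lam > 0) - 1L, union(sleep_h, charge_h))
  if (length(hrs) == 0L) stop_input("no matched waking hours under this config")
  lam <- lam[hrs + 1L]
  ep2 <- exp(cfg$between_participant_sd^2)         # E[p^2], E[p] = 1
  e_t <- mean(lam)
  e_t2 <- mean(ep2 * lam^2 * (1 + 1 / cfg$nb_size) + lam)

  ex2 <- r^2 * cw^2 + ch^2 + (r - 1)^2             # E[(r e_w - e_h)^2]
  var_d <- e_t2 * ex2 - (e_t * (r - 1))^2
  list(mean_pct_diff = as.numeric(mean_pct),
       sd_pct_diff = as.numeric(sd_pct),
       mean_hourly_diff = e_t * (r - 1),
       sd_hourly_diff = sqrt(var_d),
       e_true = e_t, e_true2 = e_t2)
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "Simulated paired-device cohort: %d participants x %d days (seed %d)\n",
    x$config$n_participants, x$config$n_days, x$config$seed))
  cat(sprintf("  hip epochs: %d rows; watch hours: %d rows (%d missing steps)\n",
              nrow(x$hip), nrow(x$watch), sum(is.na(x$watch$step_count))))
  invisible(x)
}
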