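# Independent oracles and small fixture builders used across the suite.

# Literal rule evaluator for nonwear detection: enumerate every pair of
# zero-count runs, accept the spanned interval when all interior nonzero
# runs are tolerable spikes (length <= spike, flanked by >= flank zeros on
# both sides), and mark spans of >= window minutes nonwear.
choi_oracle <- function(counts, window = 90, spike = 2, flank = 30) {
  n <- length(counts)
  wear <- rep(TRUE, n)
  r <- rle(counts == 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  zr <- which(r$values)
  for (a in seq_along(zr)) {
    for (b in seq_along(zr)) {
      if (b < a) next
      ia <- zr[a]; ib <- zr[b]
      ok <- TRUE
      if (ib > ia) {
        for (m in (ia + 1L):(ib - 1L)) {
          if (!r$values[m]) {
            if (r$lengths[m] > spike ||
                r$lengths[m - 1L] < flank || r$lengths[m + 1L] < flank) {
              ok <- FALSE
              break
            }
          }
        }
      }
      if (ok && ends[ib] - starts[ia] + 1L >= window) {
        wear[starts[ia]:ends[ib]] <- FALSE
      }
    }
  }
  wear
}

# random minute sequences with zero and nonzero bouts of varied lengths,
# tuned to exercise window/spike/flank boundaries
random_minute_sequence <- function(n_min = 600) {
  out <- integer(0)
  while (length(out) < n_min) {
    if (stats::runif(1) < 0.5) {
      len <- sample(c(5:40, 85:95, 120), 1)
      out <- c(out, integer(len))
    } else {
      len <- sample(c(1:4, 25:35, 60), 1)
      out <- c(out, 1L + stats::rpois(len, 50))
    }
  }
  out[seq_len(n_min)]
}

# ICC oracles from base-R ANOVA tables
icc1_oracle <- function(x, y) {
  n <- length(x)
  dat <- data.frame(unit = factor(rep(seq_len(n), 2)), val = c(x, y))
  ms <- stats::anova(stats::lm(val ~ unit, dat))[["Mean Sq"]]
  (ms[1] - ms[2]) / (ms[1] + ms[2])
}

icc_a1_oracle <- function(x, y) {
  n <- length(x)
  dat <- data.frame(unit = factor(rep(seq_len(n), 2)),
                    dev = factor(rep(1:2, each = n)), val = c(x, y))
  ms <- stats::anova(stats::lm(val ~ unit + dev, dat))[["Mean Sq"]]
  (ms[1] - ms[3]) / (ms[1] + ms[3] + (2 / n) * (ms[2] - ms[3]))
}

ccc_oracle <- function(x, y) {
  n <- length(x)
  sxy <- stats::cov(x, y) * (n - 1) / n
  sx2 <- stats::var(x) * (n - 1) / n
  sy2 <- stats::var(y) * (n - 1) / n
  2 * sxy / (sx2 + sy2 + (mean(x) - mean(y))^2)
}

kappa_oracle <- function(tab) {
  p <- tab / sum(tab)
  po <- sum(diag(p))
  pe <- sum(rowSums(p) * colSums(p))
  (po - pe) / (1 - pe)
}

# -- fixture builders ----------------------------------------------------

make_epochs <- function(participant_id, start, steps, activity = steps * 5L,
                        epoch_s = 30L) {
  n <- length(steps)
  out <- tibble::tibble(
    participant_id = participant_id,
    timestamp = as.POSIXct(start, tz = "UTC") + (seq_len(n) - 1L) * epoch_s,
    activity_count = as.integer(activity),
    step_count = as.integer(steps)
  )
  attr(out, "epoch_s") <- as.integer(epoch_s)
  out
}

make_watch_rows <- function(participant_id, date, hours, steps, hr) {
  tibble::tibble(
    participant_id = participant_id, date = as.Date(date),
    hour = as.integer(hours), step_count = as.integer(steps),
    hr_sample_count = as.integer(hr)
  )
}

make_roster <- function(ids, obesity = FALSE, mobility = FALSE,
                        eastern = TRUE) {
  n <- length(ids)
  ob <- rep(obesity, length.out = n)
  cov <- withr::with_seed(7919 + n, list(
    age = round(stats::runif(n, 35, 70), 1),
    height = round(stats::runif(n, 60, 75), 1),
    spread = stats::runif(n, 0, 8)
  ))
  tibble::tibble(
    participant_id = ids,
    age = cov$age,
    sex = rep(c("female", "male"), length.out = n),
    cohort = rep(c("gen3", "omni2", "nos"), length.out = n),
    height = cov$height,
    bmi = round(ifelse(ob, 31 + cov$spread / 2, 21 + cov$spread / 2), 1),
    obesity = ob,
    mobility_limitation = rep(mobility, length.out = n),
    in_eastern_time = rep(eastern, length.out = n)
  )
}

# hour-cell builders for matching tests (wear flags given directly)
make_hip_cells <- function(id, date, hours, steps) {
  tibble::tibble(
    participant_id = id, date = as.Date(date), hour = as.integer(hours),
    device = "hip", steps = as.integer(steps), hr_sample_count = NA_integer_,
    wear_minutes = ifelse(steps > 0, 60L, 0L),
    wear_daily_rule = steps > 0, wear_block_rule = steps > 0
  )
}

make_wrist_cells <- function(id, date, hours, steps, hr = 5L) {
  wrist_hour_cells(make_watch_rows(id, date, hours, steps,
                                   rep(hr, length.out = length(hours))))
}
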