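test_that("percent difference follows the symmetric-average formula", {
  expect_equal(percent_difference(1100, 900), 20)
  expect_equal(percent_difference(5000, 5000), 0)
  expect_equal(percent_difference(0, 0), 0)
  expect_equal(percent_difference(100, 0), 200)
  expect_equal(percent_difference(0, 100), -200)
  # symmetry: swapping devices flips the sign
  withr::local_seed(3)
  a <- stats::rpois(50, 400); b <- stats::rpois(50, 420)
  expect_equal(percent_difference(a, b), -percent_difference(b, a))
})

test_that("repeated-measures limits collapse and reduce correctly", {
  # constant +100 difference: LoA collapse onto the mean
  wrist <- c(1100, 2100, 3100, 1600, 2600, 900)
  hip <- wrist - 100
  id <- c("A", "A", "B", "B", "C", "C")
  ba <- bland_altman_repeated(wrist, hip, id)
  expect_equal(ba$mean_diff, 100)
  expect_equal(c(ba$loa_low, ba$loa_high), c(100, 100))

  # one pair per participant: exactly the classical limits
  withr::local_seed(8)
  w <- stats::rpois(30, 7000); h <- stats::rpois(30, 7000)
  ids <- sprintf("P%02d", 1:30)
  ba1 <- bland_altman_repeated(w, h, ids)
  d <- w - h
  expect_equal(ba1$mean_diff, mean(d))
  expect_equal(ba1$sd_total, sd(d))
  expect_equal(ba1$loa_low, mean(d) - 1.96 * sd(d))
  expect_equal(ba1$loa_high, mean(d) + 1.96 * sd(d))
})

test_that("variance components recover engineered between/within spread", {
  withr::local_seed(42)
  m <- 500; k <- 10
  id <- rep(sprintf("P%03d", 1:m), each = k)
  bias <- rep(stats::rnorm(m, 0, 200), each = k)
  d <- bias + stats::rnorm(m * k, 0, 400)
  hip <- stats::rpois(m * k, 7000)
  ba <- bland_altman_repeated(hip + d, hip, id)
  expect_lt(abs(ba$sd_total - sqrt(200^2 + 400^2)), 12)
  expect_lt(abs(sqrt(ba$var_within) - 400), 10)
})

test_that("ICC matches ANOVA mean-square oracles on random tables", {
  withr::local_seed(17)
  for (i in 1:10) {
    n <- sample(8:25, 1)
    u <- stats::rnorm(n, 0, 2)
    x <- u + stats::rnorm(n); y <- 0.2 + u + stats::rnorm(n)
    one <- icc_random_effects(x, y, "oneway")
    two <- icc_random_effects(x, y, "twoway_agreement")
    expect_equal(one$icc, icc1_oracle(x, y), tolerance = 1e-12)
    expect_equal(two$icc, icc_a1_oracle(x, y), tolerance = 1e-12)
    expect_true(one$icc >= -1 && one$icc <= 1)
    expect_true(two$icc >= -1 && two$icc <= 1)
  }
})

test_that("ICC is 1 for identical devices and penalizes constant offsets", {
  x <- c(3000, 5000, 8000, 12000, 7000)
  self <- icc_random_effects(x, x, "oneway")
  expect_equal(self$icc, 1)
  expect_equal(c(self$ci_low, self$ci_high), c(1, 1))
  off1 <- icc_random_effects(x, x + 3000, "oneway")
  offa <- icc_random_effects(x, x + 3000, "twoway_agreement")
  expect_lt(off1$icc, 1)
  expect_lt(offa$icc, 1)
  # the agreement forms are penalized even though the correlation is perfect
  expect_gt(stats::cor(x, x + 3000), 0.999)
  expect_warning(icc_random_effects(rep(5, 4), rep(5, 4)), "ICC undefined")
})

test_that("Lin concordance equals its closed form and penalizes shifts", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(lin_ccc(x, x)$ccc, 1)
  shifted <- lin_ccc(x, x + 2)
  expect_lt(shifted$ccc, 1)
  expect_equal(stats::cor(x, x + 2), 1)

  withr::local_seed(23)
  for (i in 1:10) {
    a <- stats::rnorm(10, 50, 10); b <- 0.8 * a + stats::rnorm(10, 5, 4)
    got <- lin_ccc(a, b)
    expect_equal(got$ccc, ccc_oracle(a, b), tolerance = 1e-12)
    expect_true(got$ci_low <= got$ccc && got$ccc <= got$ci_high)
  }
  expect_warning(lin_ccc(rep(2, 5), rep(2, 5)), "CCC undefined")
})

test_that("tolerance-band agreement counts and is label-symmetric", {
  expect_equal(within_tolerance(rep(5000, 8), rep(5000, 8), 15)$pct, 100)
  # (1100, 900) is a 20% difference: outside the 15% band
  wt <- within_tolerance(c(1100, 1000), c(900, 1000), 15)
  expect_equal(wt$n_within, 1L)
  # constructed 10-pair set with exactly 3 inside the band
  wrist <- c(1000, 1030, 1100, 1500, 2000, 3000, 500, 800, 400, 10)
  hip <- rep(1000, 10)
  expect_equal(within_tolerance(wrist, hip, 15)$prop, 0.3)
  expect_equal(within_tolerance(hip, wrist, 15)$prop, 0.3)
  # the band is on the symmetric scale: (1150, 1000) is 13.95%, inside;
  # (1200, 1000) is 18.2%, outside
  expect_equal(within_tolerance(1150, 1000, 15)$n_within, 1L)
  expect_equal(within_tolerance(1200, 1000, 15)$n_within, 0L)
})

test_that("threshold concordance reproduces closed-form kappa", {
  # engineered 2x2 table (40, 10; 10, 40): po=0.8, pe=0.5, kappa=0.6
  hip <- c(rep(9000, 40), rep(9000, 10), rep(4000, 10), rep(4000, 40))
  wrist <- c(rep(9000, 40), rep(4000, 10), rep(9000, 10), rep(4000, 40))
  res <- threshold_concordance(wrist, hip, thresholds = 8000)
  expect_equal(res$pct_concordant, 80)
  expect_equal(res$kappa, 0.6)
  expect_true(res$ci_low < 0.6 && 0.6 < res$ci_high)

  # degenerate margin: concordance reported, kappa undefined
  expect_warning(
    res0 <- threshold_concordance(rep(9000, 10), rep(9500, 10), thresholds = 3000),
    "kappa undefined"
  )
  expect_equal(res0$pct_concordant, 100)
  expect_true(is.na(res0$kappa))

  # random participant sets match the oracle, and p_o >= kappa(1-pe)+pe holds
  withr::local_seed(12)
  for (i in 1:10) {
    h <- stats::rlnorm(60, log(7000), 0.5)
    w <- h * stats::rlnorm(60, 0, 0.3)
    for (T in c(6000, 8000)) {
      tab <- table(factor(h >= T, c(FALSE, TRUE)), factor(w >= T, c(FALSE, TRUE)))
      res <- suppressWarnings(threshold_concordance(w, h, thresholds = T))
      ko <- kappa_oracle(tab)
      if (!is.na(res$kappa)) {
        expect_equal(res$kappa, ko, tolerance = 1e-12)
        po <- sum(diag(tab)) / sum(tab)
        pe <- (po - (1 - po) * ko / (1 - ko)) * 0 +
          sum(rowSums(tab) * colSums(tab)) / sum(tab)^2
        expect_equal(po, res$kappa * (1 - pe) + pe, tolerance = 1e-12)
      }
    }
  }
})

test_that("adjusted regression recovers slopes with clustered errors", {
  withr::local_seed(61)
  ids <- sprintf("P%02d", 1:40)
  roster <- make_roster(ids)
  pairs <- tibble::tibble(
    participant_id = rep(ids, each = 5),
    date = rep(as.Date("2017-04-02") + 0:4, 40),
    steps_hip = round(stats::rlnorm(200, log(7000), 0.4)),
    wear_diff = stats::runif(200, 0, 2)
  )
  pairs$steps_wrist <- pairs$steps_hip   # exact identity
  fit <- adjusted_slope(pairs, roster, include_wear_diff = TRUE)
  expect_equal(fit$beta, 1, tolerance = 1e-10)

  pairs$steps_wrist <- 0.9 * pairs$steps_hip +
    rep(stats::rnorm(40, 0, 150), each = 5) + stats::rnorm(200, 0, 300)
  fit2 <- adjusted_slope(pairs, roster, include_wear_diff = TRUE)
  expect_lt(abs(fit2$beta - 0.9), 2 * fit2$se)
  expect_true(fit2$ci_low < fit2$beta & fit2$beta < fit2$ci_high)

  # degenerate clustering: a single participant cannot be fit
  one <- pairs[pairs$participant_id == "P01", ]
  expect_error(adjusted_slope(one, roster))
  simple <- tibble::tibble(participant_id = "P01",
                           steps_hip = c(1000, 2000, 3000, 4000),
                           steps_wrist = c(1100, 1900, 3100, 3900),
                           date = as.Date("2017-04-02") + 0:3)
  expect_error(
    adjusted_slope(simple, roster[roster$participant_id == "P01", ],
                   covariates = "age"),
    "clusters|collinear")
})

test_that("interaction test rejects constant moderators and needs 2 devices", {
  long <- tibble::tibble(
    participant_id = rep(sprintf("P%d", 1:10), each = 2),
    steps = stats::rpois(20, 7000),
    device = rep(c("hip", "wrist"), 10),
    bmi = rep(27, 20)
  )
  expect_error(interaction_test(long, "bmi"), "constant")
  long$bmi <- rep(stats::runif(10, 20, 35), each = 2)
  long$device <- "hip"
  expect_error(interaction_test(long, "bmi"), "two levels")
})

test_that("interaction test detects an engineered device-by-BMI undercount", {
  withr::local_seed(5150)
  m <- 80; k <- 4
  bmi <- stats::runif(m, 20, 38)
  id <- rep(sprintf("P%02d", 1:m), each = 2 * k)
  hip <- round(rep(stats::rlnorm(m, log(7000), 0.3), each = 2 * k) *
                 stats::rlnorm(2 * k * m, 0, 0.1))
  long <- tibble::tibble(
    participant_id = id,
    device = rep(rep(c("hip", "wrist"), each = k), m),
    bmi = rep(bmi, each = 2 * k),
    steps = hip
  )
  und <- long$device == "wrist"
  long$steps[und] <- round(long$steps[und] * (1 - 0.02 * (long$bmi[und] - 20)))
  res <- interaction_test(long, "bmi")
  expect_lt(res$p_value, 0.01)
  expect_lt(res$estimate, 0)
})

test_that("subgroup analysis partitions participants per the table design", {
  withr::local_seed(9)
  ids <- sprintf("P%02d", 1:30)
  roster <- make_roster(ids)
  roster$obesity <- c(rep(TRUE, 8), rep(FALSE, 22))
  roster$bmi <- ifelse(roster$obesity, 33, 25)
  roster$mobility_limitation <- c(rep(FALSE, 4), rep(TRUE, 8), rep(FALSE, 18))
  pairs <- tibble::tibble(
    participant_id = rep(ids, each = 6),
    steps_hip = round(stats::rlnorm(180, log(450), 0.4)),
    steps_wrist = round(stats::rlnorm(180, log(450), 0.4))
  )
  sg <- subgroup_agreement(pairs, roster)
  got <- unique(sg$stats$subgroup)
  expect_setequal(got, c("obesity", "mobility_limitation", "neither"))
  n_neither <- unique(sg$stats$n_participants[sg$stats$subgroup == "neither"])
  expect_equal(n_neither, sum(!roster$obesity & !roster$mobility_limitation))
  # obesity and mobility groups may overlap; neither is disjoint from both
  expect_equal(
    unique(sg$stats$n_participants[sg$stats$subgroup == "obesity"]) +
      unique(sg$stats$n_participants[sg$stats$subgroup == "mobility_limitation"]),
    8 + 8
  )

  roster_none <- make_roster(ids)  # nobody obese, nobody limited
  sg2 <- NULL
  warns <- testthat::capture_warnings(
    sg2 <- subgroup_agreement(pairs, roster_none))
  expect_true(any(grepl("obesity.*skipped", warns)))
  expect_true(any(grepl("mobility_limitation.*skipped", warns)))
  expect_false("obesity" %in% sg2$stats$subgroup)
  expect_equal(sum(sg2$ledger$stage == "subgroup_obesity"), 1L)
})
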