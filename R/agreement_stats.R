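#' Symmetric percent difference between paired step counts
#'
#' `100 * (wrist - hip) / ((wrist + hip) / 2)`, the percent difference
#' relative to the two-device average. Defined as 0 when both counts are 0
#' (perfect agreement); when exactly one count is 0 the formula forces
#' +/-200.
#'
#' @param wrist,hip Numeric vectors of paired counts.
#' @return Numeric vector of percent differences.
#' @export
percent_difference <- function(wrist, hip) {
  out <- 100 * (wrist - hip) / ((wrist + hip) / 2)
  out[!is.na(wrist) & !is.na(hip) & wrist == 0 & hip == 0] <- 0
  out
}

#' Repeated-measures Bland-Altman limits of agreement
#'
#' Decomposes per-unit differences (wrist - hip), and percent differences,
#' into between-participant and within-participant variance components via
#' one-way random-effects ANOVA on the differences (Bland & Altman's
#' repeated-measures approach). The total SD is
#' `sqrt(var_between + var_within)` and the limits of agreement are
#' `mean +/- 1.96 * total SD`, on both scales. With one observation per
#' participant this reduces exactly to the classical Bland-Altman limits
#' (`mean +/- 1.96 * sample SD`).
#'
#' @param wrist,hip Paired unit values (person-days or person-hours).
#' @param participant_id Grouping vector identifying the participant of each
#'   unit.
#' @param loa_z Normal quantile for the limits (default 1.96).
#' @return A `bland_altman` list: mean_diff, loa_low, loa_high, sd_total,
#'   var_between, var_within, the same four on the percent scale
#'   (mean_pct_diff, pct_loa_low, pct_loa_high, sd_pct_total,
#'   var_pct_between, var_pct_within), n_participants, n_units.
#' @export
bland_altman_repeated <- function(wrist, hip, participant_id, loa_z = 1.96) {
  ok <- !is.na(wrist) & !is.na(hip)
  wrist <- wrist[ok]; hip <- hip[ok]
  participant_id <- as.character(participant_id[ok])
  if (length(wrist) < 2L || length(unique(participant_id)) < 2L) {
    stop_input("need >=2 participants with >=1 pair each")
  }
  d <- wrist - hip
  p <- percent_difference(wrist, hip)
  abs_part <- ba_components(d, participant_id, loa_z)
  pct_part <- ba_components(p, participant_id, loa_z)
  structure(list(
    mean_diff = abs_part$mean, loa_low = abs_part$loa[1], loa_high = abs_part$loa[2],
    sd_total = abs_part$sd_total, var_between = abs_part$var_between,
    var_within = abs_part$var_within,
    mean_pct_diff = pct_part$mean, pct_loa_low = pct_part$loa[1],
    pct_loa_high = pct_part$loa[2], sd_pct_total = pct_part$sd_total,
    var_pct_between = pct_part$var_between, var_pct_within = pct_part$var_within,
    n_participants = length(unique(participant_id)), n_units = length(d)
  ), class = "bland_altman")
}

# one-way variance components of a difference vector grouped by participant
ba_components <- function(d, g, loa_z) {
  N <- length(d)
  means <- tapply(d, g, mean)
  n_i <- tapply(d, g, length)
  m <- length(means)
  grand <- mean(d)
  if (N == m) {
    # one observation per participant: classical Bland-Altman
    v <- var(d)
    return(list(mean = grand, sd_total = sqrt(v), var_between = v,
                var_within = 0, loa = grand + c(-1, 1) * loa_z * sqrt(v)))
  }
  ssb <- sum(n_i * (means - grand)^2)
  ssw <- sum((d - means[g])^2)
  msb <- ssb / (m - 1)
  msw <- ssw / (N - m)
  n0 <- (N - sum(n_i^2) / N) / (m - 1)
  var_b <- max(0, (msb - msw) / n0)
  var_w <- msw
  sd_total <- sqrt(var_b + var_w)
  list(mean = grand, sd_total = sd_total, var_between = var_b,
       var_within = var_w, loa = grand + c(-1, 1) * loa_z * sd_total)
}

#' Intraclass correlation for two-device agreement
#'
#' Single-measures ICC from ANOVA mean squares over paired units (the unit of
#' analysis is the person-day or person-hour; the two device readings are the
#' ratings). `model = "oneway"` is ICC(1,1) from one-way random effects;
#' `model = "twoway_agreement"` is ICC(A,1), the two-way random absolute-
#' agreement form. 95% CIs use the F distribution (McGraw & Wong).
#'
#' @param x,y Paired readings (hip and wrist) per unit.
#' @param model "oneway" (default) or "twoway_agreement".
#' @param conf Confidence level (default 0.95).
#' @return List: icc, ci_low, ci_high, model, n, and the mean squares.
#' @export
icc_random_effects <- function(x, y, model = c("oneway", "twoway_agreement"),
                               conf = 0.95) {
  model <- rlang::arg_match(model)
  ok <- !is.na(x) & !is.na(y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 2L) stop_input("need >=2 units")
  k <- 2
  alpha <- 1 - conf
  vals <- cbind(x, y)
  row_means <- (x + y) / 2
  grand <- mean(vals)
  if (all(vals == grand)) {
    rlang::warn("zero total variance: ICC undefined")
    return(list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                model = model, n = n, degenerate = TRUE))
  }
  msr <- k * sum((row_means - grand)^2) / (n - 1)          # between units
  msw <- sum((vals - row_means)^2) / (n * (k - 1))         # within units
  col_means <- colMeans(vals)
  msc <- n * sum((col_means - grand)^2) / (k - 1)          # between devices
  sse <- sum((vals - outer(row_means, c(1, 1)) -
                outer(rep(1, n), col_means) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))

  if (model == "oneway") {
    icc <- (msr - msw) / (msr + (k - 1) * msw)
    if (msw == 0) {
      ci <- c(1, 1); icc <- 1
    } else {
      f <- msr / msw
      fl <- f / qf(1 - alpha / 2, n - 1, n * (k - 1))
      fu <- f * qf(1 - alpha / 2, n * (k - 1), n - 1)
      ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
    }
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
    if (mse == 0 && msc == 0) {
      ci <- c(1, 1); icc <- 1
    } else {
      a <- (k * icc) / (n * (1 - icc))
      b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
      v <- (a * msc + b * mse)^2 /
        ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
      fl <- qf(1 - alpha / 2, n - 1, v)
      fu <- qf(1 - alpha / 2, v, n - 1)
      ci <- c(
        n * (msr - fl * mse) /
          (fl * (k * msc + (k * n - k - n) * mse) + n * msr),
        n * (fu * msr - mse) /
          (k * msc + (k * n - k - n) * mse + n * fu * msr)
      )
    }
  }
  list(icc = icc, ci_low = min(ci), ci_high = max(ci), model = model, n = n,
       msr = msr, msw = msw, msc = msc, mse = mse, degenerate = FALSE)
}

#' Lin's concordance correlation coefficient
#'
#' Moment estimator `2*s_xy / (s_x^2 + s_y^2 + (mean_x - mean_y)^2)` over all
#' pooled units (the repeated-observations usage: every person-day or
#' person-hour is a unit), with Lin's Fisher-z 95% CI. Like the ICC it
#' penalizes location and scale shifts from the identity line.
#'
#' @param x,y Paired readings per unit.
#' @param conf Confidence level (default 0.95).
#' @return List: ccc, ci_low, ci_high, n.
#' @export
lin_ccc <- function(x, y, conf = 0.95) {
  ok <- !is.na(x) & !is.na(y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 3L) stop_input("need >=3 pairs")
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2)   # n-divisor moments (Lin 1989)
  sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  if (sx2 == 0 && sy2 == 0) {
    rlang::warn("zero variance in both devices: CCC undefined")
    return(list(ccc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                n = n, degenerate = TRUE))
  }
  ccc <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
  if (abs(ccc) >= 1 - 1e-15 || sx2 == 0 || sy2 == 0) {
    return(list(ccc = ccc, ci_low = ccc, ci_high = ccc, n = n,
                degenerate = FALSE))
  }
  r <- sxy / sqrt(sx2 * sy2)
  u <- (mx - my) / (sx2 * sy2)^0.25
  z <- atanh(ccc)
  se_z2 <- ((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
              2 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
              ccc^4 * u^4 / (2 * r^2 * (1 - ccc^2)^2)) / (n - 2)
  se_z <- sqrt(max(0, se_z2))
  qz <- qnorm(1 - (1 - conf) / 2)
  list(ccc = ccc, ci_low = tanh(z - qz * se_z), ci_high = tanh(z + qz * se_z),
       n = n, degenerate = FALSE)
}

#' Proportion of units within a percent-difference tolerance band
#'
#' Fraction of paired units whose absolute symmetric percent difference is at
#' most `tau` percent (15% is the lenient band; 5% the stricter one).
#' Symmetric in the device labels.
#'
#' @param wrist,hip Paired unit values.
#' @param tau Tolerance in percent (default 15).
#' @return List: prop (0-1), pct (0-100), n_within, n.
#' @export
within_tolerance <- function(wrist, hip, tau = 15) {
  ok <- !is.na(wrist) & !is.na(hip)
  if (!any(ok)) stop_input("no complete pairs")
  p <- percent_difference(wrist[ok], hip[ok])
  n_within <- sum(abs(p) <= tau)
  list(prop = n_within / sum(ok), pct = 100 * n_within / sum(ok),
       n_within = n_within, n = sum(ok), tau = tau)
}

#' Threshold concordance and Cohen's kappa
#'
#' For each steps/day threshold, cross-classifies units (participants by
#' their device-specific average daily steps, or person-days directly) as
#' meeting/not meeting the threshold on each device, and reports percent
#' concordance (both-yes + both-no) and Cohen's kappa with an asymptotic 95%
#' CI (Fleiss-Cohen-Everitt large-sample variance). Degenerate margins
#' (everyone in the same class) leave kappa undefined but concordance is
#' still reported.
#'
#' @param wrist,hip Average (or per-day) steps per unit for each device.
#' @param thresholds Steps/day thresholds (default `c(3000, 6000, 8000,
#'   10000)`).
#' @param conf Confidence level (default 0.95).
#' @return Tibble: threshold, pct_concordant, n_concordant, kappa, ci_low,
#'   ci_high, n, plus a `contingency` list-column of 2x2 tables.
#' @export
threshold_concordance <- function(wrist, hip,
                                  thresholds = c(3000, 6000, 8000, 10000),
                                  conf = 0.95) {
  ok <- !is.na(wrist) & !is.na(hip)
  wrist <- wrist[ok]; hip <- hip[ok]
  n <- length(wrist)
  if (n < 2L) stop_input("need >=2 units")
  rows <- lapply(thresholds, function(T) {
    a <- factor(hip >= T, levels = c(FALSE, TRUE))
    b <- factor(wrist >= T, levels = c(FALSE, TRUE))
    tab <- table(hip = a, wrist = b)
    kp <- kappa_2x2(tab, conf)
    tibble::tibble(
      threshold = T,
      n_concordant = sum(diag(tab)),
      pct_concordant = 100 * sum(diag(tab)) / n,
      kappa = kp$kappa, ci_low = kp$ci_low, ci_high = kp$ci_high,
      n = n, contingency = list(tab)
    )
  })
  dplyr::bind_rows(rows)
}

# Cohen's kappa with Fleiss-Cohen-Everitt asymptotic CI for an r x r table
kappa_2x2 <- function(tab, conf = 0.95) {
  n <- sum(tab)
  p <- tab / n
  po <- sum(diag(p))
  pr <- rowSums(p); pc <- colSums(p)
  pe <- sum(pr * pc)
  if (abs(1 - pe) < 1e-12) {
    rlang::warn("degenerate margins: kappa undefined")
    return(list(kappa = NA_real_, ci_low = NA_real_, ci_high = NA_real_))
  }
  kappa <- (po - pe) / (1 - pe)
  r <- nrow(p)
  t1 <- 0; t2 <- 0
  for (i in seq_len(r)) {
    t1 <- t1 + p[i, i] * ((1 - pe) - (pc[i] + pr[i]) * (1 - po))^2
    for (j in seq_len(r)) {
      if (i != j) t2 <- t2 + p[i, j] * (pc[i] + pr[j])^2
    }
  }
  t2 <- (1 - po)^2 * t2
  t3 <- (po * pe - 2 * pe + po)^2
  var_k <- (t1 + t2 - t3) / (n * (1 - pe)^4)
  se <- sqrt(max(0, var_k))
  qz <- qnorm(1 - (1 - conf) / 2)
  list(kappa = kappa, ci_low = kappa - qz * se, ci_high = kappa + qz * se)
}

#' Covariate-adjusted regression of wrist on hip steps
#'
#' Least-squares regression of wrist steps on hip steps plus roster
#' covariates (age, sex, cohort, BMI, height by default, optionally the
#' between-device wear-time difference), with the 95% CI for the slope from
#' cluster-robust (CR1, clustered by participant) standard errors.
#'
#' @param pairs Paired-unit tibble with `steps_wrist`, `steps_hip`,
#'   `participant_id` (and `wear_diff` if requested).
#' @param roster Roster tibble.
#' @param covariates Roster columns to adjust for.
#' @param include_wear_diff Add the wear-time difference (sample-1 models).
#' @param cluster_by_participant Use cluster-robust SEs (default TRUE).
#' @param conf Confidence level.
#' @return List: beta, ci_low, ci_high, se, df, coefficients, n,
#'   n_participants.
#' @export
adjusted_slope <- function(pairs, roster,
                           covariates = c("age", "sex", "cohort", "bmi", "height"),
                           include_wear_diff = FALSE,
                           cluster_by_participant = TRUE, conf = 0.95) {
  dat <- dplyr::inner_join(pairs, roster, by = "participant_id")
  if (nrow(dat) < nrow(pairs)) {
    stop_input("roster is missing participants present in pairs")
  }
  rhs <- c("steps_hip", covariates, if (include_wear_diff) "wear_diff")
  fml <- stats::as.formula(paste("steps_wrist ~", paste(rhs, collapse = " + ")))
  fit <- cluster_lm(fml, dat, cluster = if (cluster_by_participant)
    dat$participant_id else NULL, conf = conf)
  b <- fit$coefficients["steps_hip", ]
  list(beta = b[["estimate"]], ci_low = b[["ci_low"]], ci_high = b[["ci_high"]],
       se = b[["se"]], df = fit$df, coefficients = fit$coefficients,
       n = nrow(dat), n_participants = length(unique(dat$participant_id)))
}

#' Device-by-moderator interaction test
#'
#' Fits, on a long-format table with two rows per unit (one per device), a
#' regression of steps on device, moderator and their interaction (plus
#' optional covariates), with cluster-robust standard errors by participant,
#' and returns the interaction coefficient and p-value. Moderators of
#' interest: wear time, age, sex, height, BMI, obesity, mobility limitation.
#'
#' @param long Long tibble with columns `participant_id`, `steps`, `device`
#'   (two levels) and the moderator (plus covariates).
#' @param moderator Name of the moderator column.
#' @param covariates Optional additional adjustment columns.
#' @param conf Confidence level.
#' @return List: estimate, se, p_value, ci_low, ci_high, term, df.
#' @export
interaction_test <- function(long, moderator, covariates = NULL, conf = 0.95) {
  assert_cols(long, c("participant_id", "steps", "device", moderator),
              "long table")
  mod_vals <- long[[moderator]]
  if (length(unique(mod_vals[!is.na(mod_vals)])) < 2L) {
    stop_input(sprintf("moderator '%s' is constant", moderator))
  }
  if (length(unique(long$device)) != 2L) {
    stop_input("'device' must have exactly two levels")
  }
  rhs <- c(sprintf("device * %s", moderator), covariates)
  fml <- stats::as.formula(paste("steps ~", paste(rhs, collapse = " + ")))
  fit <- cluster_lm(fml, long, cluster = long$participant_id, conf = conf)
  cn <- rownames(fit$coefficients)
  term <- cn[grepl(":", cn, fixed = TRUE)]
  if (length(term) != 1L) term <- term[1L]
  b <- fit$coefficients[term, ]
  list(estimate = b[["estimate"]], se = b[["se"]], p_value = b[["p_value"]],
       ci_low = b[["ci_low"]], ci_high = b[["ci_high"]], term = term,
       df = fit$df)
}

# least squares with optional CR1 cluster-robust vcov; returns a coefficient
# table (estimate, se, ci, p) using t with (n_clusters - 1) df when clustered
cluster_lm <- function(formula, data, cluster = NULL, conf = 0.95) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.fail)
  X <- stats::model.matrix(formula, mf)
  y <- stats::model.response(mf)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    aliased <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    stop_input("rank-deficient design; collinear column(s): ",
               paste(aliased, collapse = ", "))
  }
  beta <- qr.coef(qrx, y)
  res <- y - X %*% beta
  n <- nrow(X); k <- ncol(X)
  XtXinv <- chol2inv(qr.R(qrx))
  dimnames(XtXinv) <- list(colnames(X), colnames(X))
  if (is.null(cluster)) {
    sigma2 <- sum(res^2) / (n - k)
    V <- sigma2 * XtXinv
    df <- n - k
  } else {
    cluster <- as.character(cluster)
    m <- length(unique(cluster))
    if (m < 2L) stop_input("cluster-robust errors need >=2 clusters")
    Xe <- X * as.numeric(res)
    meat_half <- rowsum(Xe, cluster)
    meat <- crossprod(meat_half)
    adj <- (m / (m - 1)) * ((n - 1) / (n - k))
    V <- adj * XtXinv %*% meat %*% XtXinv
    df <- m - 1
  }
  se <- sqrt(diag(V))
  tval <- beta / se
  qz <- qt(1 - (1 - conf) / 2, df)
  coefs <- cbind(estimate = beta, se = se,
                 ci_low = beta - qz * se, ci_high = beta + qz * se,
                 p_value = 2 * pt(-abs(tval), df))
  list(coefficients = coefs, df = df, vcov = V, n = n)
}

#' Full agreement-statistics suite for one set of pairs
#'
#' Computes the ICC (one-way and two-way agreement forms), Lin's CCC,
#' repeated-measures Bland-Altman limits (absolute and percent scale), and
#' tolerance-band agreement, returning a tidy statistics table plus detail
#' objects. This is the per-sample (and per-subgroup) workhorse behind
#' [run_pipeline()].
#'
#' @param wrist,hip Paired unit values.
#' @param participant_id Participant of each unit.
#' @param sample,subgroup Labels recorded in the output rows.
#' @param tolerances Percent tolerance bands (default `c(15, 5)`).
#' @return List: `stats` (tidy tibble), `details` (variance components).
#' @export
agreement_suite <- function(wrist, hip, participant_id, sample = "sample",
                            subgroup = "all", tolerances = c(15, 5)) {
  n_p <- length(unique(participant_id))
  n_u <- length(wrist)
  icc1 <- icc_random_effects(hip, wrist, "oneway")
  icca <- icc_random_effects(hip, wrist, "twoway_agreement")
  ccc <- lin_ccc(hip, wrist)
  ba <- bland_altman_repeated(wrist, hip, participant_id)
  row <- function(statistic, estimate, lo = NA_real_, hi = NA_real_) {
    tibble::tibble(sample = sample, subgroup = subgroup, statistic = statistic,
                   estimate = estimate, ci_low = lo, ci_high = hi,
                   n_participants = n_p, n_units = n_u)
  }
  stats_tbl <- dplyr::bind_rows(
    row("icc_oneway", icc1$icc, icc1$ci_low, icc1$ci_high),
    row("icc_twoway_agreement", icca$icc, icca$ci_low, icca$ci_high),
    row("lin_ccc", ccc$ccc, ccc$ci_low, ccc$ci_high),
    row("mean_diff", ba$mean_diff, ba$loa_low, ba$loa_high),
    row("mean_pct_diff", ba$mean_pct_diff, ba$pct_loa_low, ba$pct_loa_high),
    dplyr::bind_rows(lapply(tolerances, function(tau) {
      wt <- within_tolerance(wrist, hip, tau)
      row(sprintf("pct_within_%g", tau), wt$pct)
    }))
  )
  list(stats = stats_tbl,
       details = list(bland_altman = unclass(ba),
                      icc_oneway = icc1, icc_twoway = icca, ccc = ccc))
}

#' Agreement suite by clinical subgroup
#'
#' Repeats the agreement suite in the subgroups used for the person-hour
#' sample: participants with obesity (2A), with mobility limitations (2B) -
#' these two may overlap - and with neither (2C).
#'
#' @param pairs Paired-unit tibble (`steps_wrist`, `steps_hip`,
#'   `participant_id`).
#' @param roster Roster with `obesity` and `mobility_limitation`.
#' @param sample Label prefix for output rows.
#' @param tolerances Percent tolerance bands.
#' @return List: `stats` (bound rows for all non-empty subgroups), `details`,
#'   `ledger` (empty subgroups noted).
#' @export
subgroup_agreement <- function(pairs, roster, sample = "sample2",
                               tolerances = c(15, 5)) {
  groups <- list(
    obesity = roster$participant_id[roster$obesity],
    mobility_limitation = roster$participant_id[roster$mobility_limitation],
    neither = roster$participant_id[!roster$obesity & !roster$mobility_limitation]
  )
  ledger <- ledger_new()
  stats_all <- list(); details <- list()
  for (g in names(groups)) {
    sub <- pairs[pairs$participant_id %in% groups[[g]], ]
    if (nrow(sub) == 0L || length(unique(sub$participant_id)) < 2L) {
      rlang::warn(sprintf("subgroup '%s' empty or single-participant; skipped", g))
      ledger <- ledger_add(ledger, paste0("subgroup_", g),
                           "subgroup empty or too small; skipped")
      next
    }
    res <- agreement_suite(sub$steps_wrist, sub$steps_hip, sub$participant_id,
                           sample = sample, subgroup = g,
                           tolerances = tolerances)
    stats_all[[g]] <- res$stats
    details[[g]] <- res$details
  }
  list(stats = dplyr::bind_rows(stats_all), details = details, ledger = ledger)
}
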