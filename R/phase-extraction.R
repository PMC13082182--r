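#' Aggregate raw heart-rate samples into a weekly 5-minute profile
#'
#' Maps every sample to minutes since the most recent Sunday 00:00 (local
#' wall-clock), floors to the containing 5-minute bin, and averages bpm over
#' all samples falling in each bin across all available dates. A fully
#' covered week yields 2016 bins (288 per day for 7 days); bins with no
#' samples are omitted.
#'
#' @param hr Tibble of raw samples with columns `timestamp` (POSIXct or
#'   ISO-8601 string) and `bpm`, and optionally `participant_id` for a
#'   multi-participant table.
#' @return Tibble with columns `bin_start` (minutes-of-week, multiples of 5
#'   in 0..10075), `mean_hr`, `n_samples`, grouped rows per participant when
#'   `participant_id` is present. Empty input gives an empty profile.
#' @export
aggregate_weekly_profile <- function(hr) {
  assert_cols(hr, c("timestamp", "bpm"))
  if (nrow(hr) == 0) {
    out <- tibble::tibble(bin_start = integer(0), mean_hr = numeric(0),
                          n_samples = integer(0))
    if ("participant_id" %in% names(hr)) {
      out <- tibble::add_column(out, participant_id = character(0), .before = 1)
    }
    return(out)
  }
  ts <- hr$timestamp
  if (!inherits(ts, "POSIXt")) ts <- as.POSIXct(ts, tz = "UTC")
  lt <- as.POSIXlt(ts)
  mow <- lt$wday * 1440L + lt$hour * 60L + lt$min
  bin <- (mow %/% 5L) * 5L

  df <- tibble::tibble(bin_start = bin, bpm = hr$bpm)
  keys <- "bin_start"
  if ("participant_id" %in% names(hr)) {
    df$participant_id <- hr$participant_id
    keys <- c("participant_id", "bin_start")
  }
  df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(mean_hr = mean(.data$bpm),
                     n_samples = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(keys)))
}

# Closed-form least-squares sine fit for one profile.
# Returns c(A, phi, b, r_squared, n_bins, ok, a, c).
sine_fit_one <- function(bin_start, mean_hr) {
  t <- bin_start
  y <- mean_hr
  nb <- length(t)
  fail <- c(A = NA_real_, phi = NA_real_, b = NA_real_,
            r_squared = NA_real_, n_bins = nb, ok = 0)
  if (nb < 3 || length(unique(t %% 1440)) < 3) return(fail)
  w <- pi / 720
  X <- cbind(1, sin(w * t), cos(w * t))
  fit <- .lm.fit(X, y)
  cf <- fit$coefficients
  b <- cf[1]; a <- cf[2]; cc <- cf[3]
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  A <- sqrt(a^2 + cc^2)
  phi <- wrap24((atan2(-cc, a) * 720 / pi) / 60)
  if (ss_tot <= 0) {
    # constant profile: amplitude indistinguishable from 0, flag the fit
    return(c(A = 0, phi = NA_real_, b = mean(y), r_squared = 0,
             n_bins = nb, ok = 0))
  }
  r2 <- 1 - ss_res / ss_tot
  c(A = A, phi = phi, b = b, r_squared = r2, n_bins = nb, ok = 1)
}

#' Fit a fixed-period 24 h sine curve to a weekly heart-rate profile
#'
#' Fits \deqn{HR = A\sin(\pi/720\,(t-\varphi_{min})) + b} by unweighted least
#' squares on the linear basis \{sin, cos, 1\} over the profile's bins, then
#' converts to the canonical parameterisation with amplitude \eqn{A \ge 0}
#' and phase \eqn{\varphi \in [0, 24)} hours. Because the basis is linear in
#' the parameters the fit is the exact global least-squares optimum; phase is
#' the ascending mean-crossing time and the heart-rate peak occurs at
#' \eqn{\varphi + 6} h.
#'
#' Profiles with fewer than 3 bins at distinct times-of-day cannot identify
#' the three parameters and are flagged (`fit_ok = FALSE`), as are constant
#' profiles, whose `r_squared` is defined as 0.
#'
#' @param profile Output of [aggregate_weekly_profile()]; one participant, or
#'   a cohort table with a `participant_id` column.
#' @return One-row tibble per participant with columns `A` (bpm), `phi`
#'   (hours in \[0,24)), `b` (bpm), `r_squared`, `n_bins`, `fit_ok`.
#' @export
fit_sine <- function(profile) {
  assert_cols(profile, c("bin_start", "mean_hr"))
  shape <- function(v) {
    tibble::tibble(A = v[["A"]], phi = v[["phi"]], b = v[["b"]],
                   r_squared = v[["r_squared"]],
                   n_bins = as.integer(v[["n_bins"]]),
                   fit_ok = v[["ok"]] == 1)
  }
  if (!"participant_id" %in% names(profile)) {
    return(shape(sine_fit_one(profile$bin_start, profile$mean_hr)))
  }
  profile |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(~ shape(sine_fit_one(.x$bin_start, .x$mean_hr))) |>
    dplyr::ungroup()
}

#' Predicted heart rate from canonical sine parameters
#'
#' @param A,phi,b Canonical parameters (amplitude bpm, phase hours, shift bpm).
#' @param t_min Time in minutes.
#' @return Predicted bpm.
#' @export
sine_predict <- function(A, phi, b, t_min) {
  A * sin(pi / 720 * (t_min - 60 * phi)) + b
}

#' Count distinct calendar days with heart-rate data
#'
#' @param hr Raw heart-rate table (`participant_id`, `timestamp`).
#' @return Tibble `participant_id`, `days_with_data`.
#' @export
hr_days_with_data <- function(hr) {
  assert_cols(hr, c("participant_id", "timestamp"))
  ts <- hr$timestamp
  if (!inherits(ts, "POSIXt")) ts <- as.POSIXct(ts, tz = "UTC")
  tibble::tibble(participant_id = hr$participant_id,
                 date = as.Date(ts)) |>
    dplyr::distinct() |>
    dplyr::count(.data$participant_id, name = "days_with_data")
}

#' Extract per-participant heart-rate phase from a raw sample table
#'
#' Convenience wrapper: weekly aggregation, sine fitting and day counting in
#' one call.
#'
#' @param hr Raw heart-rate table (`participant_id`, `timestamp`, `bpm`).
#' @return Tibble with the [fit_sine()] columns plus `days_with_data`.
#' @export
extract_phases <- function(hr) {
  fits <- fit_sine(aggregate_weekly_profile(hr))
  dplyr::left_join(fits, hr_days_with_data(hr), by = "participant_id") |>
    dplyr::mutate(days_with_data = dplyr::coalesce(.data$days_with_data, 0L))
}

#' Scan goodness-of-fit thresholds by a Youden-style retention index
#'
#' For each candidate threshold \eqn{\theta} the retention rate is the number
#' of participants with \eqn{R^2 > \theta} divided by the number with
#' \eqn{R^2 > 0}; the Youden index is retention \eqn{+\ \theta - 1}. The
#' selected threshold maximises the index, with ties broken toward the
#' lowest threshold.
#'
#' @param fits Cohort fit table from [fit_sine()] or [extract_phases()]
#'   (needs `r_squared`; `NA` values, i.e. failed fits, are ignored).
#' @param grid_step Spacing of the threshold grid (default 0.1 over
#'   0.0–0.9).
#' @param grid Optional explicit threshold grid, overriding `grid_step`.
#' @return Tibble of class `hrp_threshold_scan` with columns `threshold`,
#'   `n_retained`, `retention`, `youden`; the chosen threshold is in
#'   `attr(, "selected")` and via [selected_threshold()].
#' @export
select_r2_threshold <- function(fits, grid_step = 0.1, grid = NULL) {
  assert_cols(fits, "r_squared")
  r2 <- fits$r_squared[!is.na(fits$r_squared)]
  if (length(r2) == 0) stop("no fitted participants", call. = FALSE)
  if (is.null(grid)) grid <- seq(0, 0.9, by = grid_step)
  denom <- sum(r2 > 0)
  if (denom == 0) stop("no participants with r_squared > 0", call. = FALSE)
  n_ret <- vapply(grid, function(th) sum(r2 > th), integer(1))
  retention <- n_ret / denom
  youden <- retention + grid - 1
  out <- tibble::tibble(threshold = grid, n_retained = n_ret,
                        retention = retention, youden = youden)
  attr(out, "selected") <- grid[which.max(youden)]
  class(out) <- c("hrp_threshold_scan", class(out))
  out
}

#' @rdname select_r2_threshold
#' @param scan A threshold scan.
#' @export
selected_threshold <- function(scan) attr(scan, "selected")

#' Apply the cohort inclusion filters
#'
#' Three filters applied in order: (1) more than `min_days` distinct calendar
#' days of heart-rate data (participants with exactly `min_days` days are
#' excluded); (2) sine-fit \eqn{R^2} strictly above `threshold`; (3) on the
#' survivors of (1) and (2), phase outliers with
#' \eqn{|\varphi - \bar\varphi| \ge 3\,SD(\varphi)} are excluded, where mean
#' and SD are linear statistics in hours computed once over those survivors.
#' If the survivor SD is 0 (all phases identical) no one is excluded by step
#' 3. Failed fits (`NA` \eqn{R^2}) are excluded at step 2.
#'
#' @param fits Table from [extract_phases()] (or [fit_sine()] joined with day
#'   counts): columns `participant_id`, `phi`, `r_squared`, `days_with_data`.
#' @param covariates Optional covariate table joined onto the result by
#'   `participant_id`.
#' @param threshold \eqn{R^2} inclusion threshold (strict >; default 0.5).
#' @param min_days Day-count threshold (strict >; default 30).
#' @param sd_mult Outlier multiple of the phase SD (default 3).
#' @return Cohort tibble with `included` (logical) and `exclusion_reason`
#'   (`NA`, `"days"`, `"r_squared"` or `"phase_outlier"`).
#' @export
apply_inclusion_filters <- function(fits, covariates = NULL, threshold = 0.5,
                                    min_days = 30, sd_mult = 3) {
  assert_cols(fits, c("participant_id", "phi", "r_squared", "days_with_data"))
  out <- tibble::as_tibble(fits)
  reason <- rep(NA_character_, nrow(out))
  pass_days <- out$days_with_data > min_days
  reason[!pass_days] <- "days"
  pass_r2 <- !is.na(out$r_squared) & out$r_squared > threshold
  reason[pass_days & !pass_r2] <- "r_squared"
  surv <- pass_days & pass_r2
  if (any(surv)) {
    mu <- mean(out$phi[surv])
    sigma <- sd(out$phi[surv])
    if (!is.na(sigma) && sigma > 0) {
      outlier <- surv & abs(out$phi - mu) >= sd_mult * sigma
      reason[outlier] <- "phase_outlier"
      surv <- surv & !outlier
    }
  }
  out$included <- surv
  out$exclusion_reason <- reason
  if (!is.null(covariates)) {
    out <- dplyr::left_join(out, covariates, by = "participant_id")
  }
  out
}
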