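# Weekly binning, sine fitting, threshold selection and inclusion filters.

test_that("samples map to 5-min minutes-of-week bins with within-bin means", {
  # single sample Sunday 00:03 -> bin 0
  hr1 <- tibble::tibble(
    timestamp = as.POSIXct("2021-01-03 00:03:00", tz = "UTC"), # a Sunday
    bpm = 70
  )
  p1 <- aggregate_weekly_profile(hr1)
  expect_equal(p1$bin_start, 0L)
  expect_equal(p1$mean_hr, 70)

  # Monday 00:01 and 00:04 share bin 1440 and average to 70
  hr2 <- tibble::tibble(
    timestamp = as.POSIXct(c("2021-01-04 00:01:00", "2021-01-04 00:04:00"),
                           tz = "UTC"),
    bpm = c(60, 80)
  )
  p2 <- aggregate_weekly_profile(hr2)
  expect_equal(p2$bin_start, 1440L)
  expect_equal(p2$mean_hr, 70)
  expect_equal(p2$n_samples, 2L)

  # empty input -> empty profile
  expect_equal(nrow(aggregate_weekly_profile(hr1[0, ])), 0)
})

test_that("a fully covered week yields exactly 2016 bins", {
  ts <- as.POSIXct("2021-01-03 00:00:00", tz = "UTC") +
    seq(0, 7 * 1440 - 5, by = 5) * 60
  hr <- tibble::tibble(timestamp = ts, bpm = 70 + sin(seq_along(ts)))
  prof <- aggregate_weekly_profile(hr)
  expect_equal(nrow(prof), 2016)
  expect_true(all(prof$bin_start %% 5 == 0))
  expect_equal(range(prof$bin_start), c(0L, 10075L))
})

test_that("a noiseless profile is inverted exactly", {
  prof <- make_profile(A = 10, phi = 9.5, b = 70)
  fit <- fit_sine(prof)
  expect_equal(fit$A, 10, tolerance = 1e-9)
  expect_equal(fit$phi, 9.5, tolerance = 1e-9)
  expect_equal(fit$b, 70, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_true(fit$fit_ok)
})

test_that("degenerate profiles are flagged", {
  const <- tibble::tibble(bin_start = seq(0, 1000, by = 5), mean_hr = 70)
  fit <- fit_sine(const)
  expect_equal(fit$A, 0)
  expect_equal(fit$r_squared, 0)
  expect_false(fit$fit_ok)

  tiny <- tibble::tibble(bin_start = c(0, 5), mean_hr = c(70, 71))
  expect_false(fit_sine(tiny)$fit_ok)

  # bins at distinct minutes-of-week but identical time-of-day are unusable
  alias <- tibble::tibble(bin_start = c(0, 1440, 2880, 4320),
                          mean_hr = c(70, 71, 70, 71))
  expect_false(fit_sine(alias)$fit_ok)
})

test_that("linear-basis fit matches the exhaustive grid-search oracle", {
  for (s in 1:5) {
    prof <- make_profile(A = 8, phi = 10.2, b = 72, noise_sd = 2, seed = s)
    fit <- fit_sine(prof)
    oracle <- grid_fit_oracle(prof$bin_start, prof$mean_hr)
    expect_lt(abs(fit$phi - oracle$phi), 1e-6)
    expect_lt(abs(fit$A - oracle$A), 1e-6)
    expect_lt(abs(fit$b - oracle$b), 1e-6)
    expect_lt(abs(fit$phi - 10.2), 0.05)
  }
})

test_that("fits are invariant to whole-period shifts in t", {
  prof <- make_profile(A = 9, phi = 8.3, b = 68, noise_sd = 1, seed = 2)
  shifted <- prof |> dplyr::mutate(bin_start = bin_start + 3 * 1440)
  f1 <- fit_sine(prof)
  f2 <- fit_sine(shifted)
  expect_equal(f1$A, f2$A, tolerance = 1e-10)
  expect_equal(f1$phi, f2$phi, tolerance = 1e-10)
  expect_equal(f1$b, f2$b, tolerance = 1e-10)
})

test_that("threshold scan follows the retention-plus-threshold rule", {
  # all fits perfect: retention 1 everywhere, youden = theta, pick max
  fits <- tibble::tibble(r_squared = rep(1, 50))
  scan <- select_r2_threshold(fits)
  expect_equal(scan$retention, rep(1, 10))
  expect_equal(scan$youden, scan$threshold)
  expect_equal(selected_threshold(scan), 0.9)

  # uniform r2: verified against direct counting, ties break low
  set.seed(31)
  r2 <- runif(5000)
  scan <- select_r2_threshold(tibble::tibble(r_squared = r2))
  grid <- seq(0, 0.9, by = 0.1)
  oracle_ret <- sapply(grid, function(th) sum(r2 > th)) / sum(r2 > 0)
  expect_equal(scan$retention, oracle_ret)
  oracle_youden <- oracle_ret + grid - 1
  expect_equal(selected_threshold(scan), grid[which.max(oracle_youden)])
  expect_lt(max(abs(oracle_ret - (1 - grid))), 0.03)

  # retention is non-increasing in the threshold
  expect_true(all(diff(scan$retention) <= 0))
  expect_error(select_r2_threshold(tibble::tibble(r_squared = numeric(0))),
               "no fitted")
})

test_that("inclusion filters apply the three rules in order", {
  fits <- tibble::tibble(
    participant_id = sprintf("P%03d", 1:104),
    phi = c(rep(9.0, 100), 20.0, 9.1, 9.2, 9.3),
    r_squared = c(rep(0.8, 101), 0.5, 0.3, 0.8),
    days_with_data = c(rep(60L, 102), 60L, 30L)
  )
  out <- apply_inclusion_filters(fits, threshold = 0.5, min_days = 30)

  # boundary: exactly 30 days is excluded, reason recorded
  expect_false(out$included[104])
  expect_equal(out$exclusion_reason[104], "days")
  # r2 at and below the threshold are excluded (strict >)
  expect_equal(out$exclusion_reason[102], "r_squared")
  expect_equal(out$exclusion_reason[103], "r_squared")

  # outlier decision must equal the brute-force 3-SD rule computed once
  # over the survivors of the first two filters
  surv_phi <- fits$phi[1:101]
  mu <- mean(surv_phi); sigma <- sd(surv_phi)
  expected_out <- abs(fits$phi[1:101] - mu) >= 3 * sigma
  expect_equal(!is.na(out$exclusion_reason[1:101]) &
                 out$exclusion_reason[1:101] == "phase_outlier", expected_out)
  expect_equal(sum(out$included), 101 - sum(expected_out))
})

test_that("identical phases disable the SD-based outlier rule", {
  fits <- tibble::tibble(participant_id = sprintf("P%02d", 1:20),
                         phi = rep(9, 20), r_squared = 0.9,
                         days_with_data = 50L)
  out <- apply_inclusion_filters(fits)
  expect_true(all(out$included))
})

test_that("phase recovery under noise and missingness is accurate", {
  cfg <- sim_config(n_participants = 30, n_days = 30, hr_noise_sd = 5,
                    missingness_rate = 0.2, seed = 17)
  sim <- simulate_cohort(cfg)
  fits <- extract_phases(sim$hr)
  err <- abs(fits$phi - (sim$truth$phase %% 24))
  err <- pmin(err, 24 - err)
  expect_lt(median(err), 0.1)
})
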