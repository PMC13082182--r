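# Disease flags, HbA1c processing, logistic risk, Cox models, comparisons.

test_that("condition flags use the unlimited-depth closure", {
  # chain 1 -> 2 -> 3 -> 4 -> 5: occurrence at depth 4 still flags concept 1
  chain <- tibble::tibble(parent_id = 1:4, child_id = 2:5)
  occ <- tibble::tibble(participant_id = c("a", "b"), concept_id = c(5, 99))
  flags <- flag_condition(occ[1, ], chain, 1, participants = c("a", "b"))
  expect_equal(flags$flag[flags$participant_id == "a"], 1L)
  expect_equal(flags$flag[flags$participant_id == "b"], 0L)
})

test_that("condition flags equal BFS-oracle reachability on random trees", {
  for (s in 1:5) {
    edges <- random_tree(30, seed = s)
    set.seed(s + 100)
    occ <- tibble::tibble(
      participant_id = sprintf("p%d", sample(1:40, 60, replace = TRUE)),
      concept_id = as.numeric(sample(1:30, 60, replace = TRUE))
    )
    node <- sample(1:30, 1)
    flags <- flag_condition(occ, edges, node,
                            participants = sprintf("p%d", 1:40))
    closure <- bfs_closure_oracle(edges, node, Inf)
    expected <- sprintf("p%d", 1:40) %in%
      occ$participant_id[occ$concept_id %in% closure]
    expect_equal(flags$flag, as.integer(expected))
  }
})

test_that("maximum HbA1c respects the range filter and the monitoring end", {
  labs <- tibble::tibble(
    participant_id = c("a", "a", "a", "b", "c"),
    date = as.Date(c("2021-01-01", "2021-02-01", "2021-06-01",
                     "2021-01-15", "2021-01-15")),
    hba1c_pct = c(5.4, 6.1, 7.0, 0.5, 5.6)
  )
  ends <- tibble::tibble(participant_id = c("a", "b", "c"),
                         monitoring_end = as.Date("2021-03-01"))
  out <- max_hba1c_before_end(labs, ends)
  a <- out[out$participant_id == "a", ]
  expect_equal(a$max_hba1c, 6.1) # 7.0 is after monitoring end
  expect_true(a$elevated)
  # 0.5 is outside the 1-30% plausibility range -> no qualifying value
  expect_true(is.na(out$max_hba1c[out$participant_id == "b"]))
  # exactly 5.6 is not elevated (strict >)
  expect_false(out$elevated[out$participant_id == "c"])
})

test_that("a measurement dated on the monitoring end day is excluded", {
  labs <- tibble::tibble(participant_id = "a", date = as.Date("2021-03-01"),
                         hba1c_pct = 6)
  ends <- tibble::tibble(participant_id = "a",
                         monitoring_end = as.Date("2021-03-01"))
  expect_true(is.na(max_hba1c_before_end(labs, ends)$max_hba1c))
})

test_that("univariate logistic OR matches the 2x2 cross-product", {
  df <- tibble::tibble(
    exposed = rep(c(1, 0), c(100, 100)),
    case = c(rep(1, 20), rep(0, 80), rep(1, 10), rep(0, 90))
  )
  res <- logistic_risk(df, "case", "exposed", covariates = character(0))
  expect_equal(res$or, (20 * 90) / (80 * 10), tolerance = 1e-6) # 2.25
})

test_that("a null exposure gives an odds ratio near 1", {
  n <- 4000
  df <- make_covars(n, seed = 7)
  set.seed(7)
  df$phi <- rnorm(n, 9.5, 1.5)
  df$y <- rbinom(n, 1, 0.2)
  res <- logistic_risk(df, "y", "phi")
  expect_lt(abs(res$beta), 3 * res$se)
  expect_error(logistic_risk(df |> dplyr::mutate(y = 0), "y", "phi"),
               "does not vary")
})

make_surv_data <- function(n = 3000, loghr = 0.17, seed = 5) {
  df <- make_covars(n, seed = seed)
  set.seed(seed + 1)
  df$phi <- rnorm(n, 9.5, 1.5)
  rate <- 0.004 * exp(loghr * (df$phi - 9.5))
  t_event <- 20 + rexp(n, rate)
  censor <- pmin(df$age, 75)
  df$event <- as.integer(t_event <= censor)
  df$age_at_event_or_censor <- pmin(t_event, censor)
  df
}

test_that("Cox on the age scale recovers a null and is affine-invariant", {
  df <- make_surv_data(n = 3000, loghr = 0, seed = 5)
  res <- cox_age_at_diagnosis(df, "phi")
  expect_lt(abs(res$loghr), 3 * res$se)

  # shifting the age origin leaves the partial-likelihood estimate unchanged
  df2 <- df |> dplyr::mutate(age_at_event_or_censor = age_at_event_or_censor + 7)
  res2 <- cox_age_at_diagnosis(df2, "phi")
  expect_equal(res2$loghr, res$loghr, tolerance = 1e-8)
})

test_that("a single stratum reproduces the unstratified fit", {
  df <- make_surv_data(n = 2000, loghr = 0.17, seed = 6)
  df$y_chromosome <- FALSE
  res <- cox_age_at_diagnosis(df, "phi")
  plain <- survival::coxph(
    survival::Surv(age_at_event_or_censor, event) ~ phi + weekly_steps +
      pc1 + pc2 + pc3 + pc4 + pc5, data = df)
  expect_equal(res$loghr, unname(coef(plain)["phi"]), tolerance = 1e-8)
})

test_that("the post-monitoring subgroup drops pre-monitoring diagnoses only", {
  df <- make_surv_data(n = 1000, loghr = 0.17, seed = 9)
  df$monitoring_start_age <- df$age - 2
  res_all <- cox_age_at_diagnosis(df, "phi")
  res_sub <- cox_age_at_diagnosis(df, "phi", subgroup = "post_monitoring")
  n_pre <- sum(df$event == 1 &
                 df$age_at_event_or_censor <= df$monitoring_start_age)
  expect_equal(res_sub$n, res_all$n - n_pre)
  expect_true(all(res_sub$n_events <= res_all$n_events))
})

test_that("group comparisons report Welch/Mann-Whitney with Cohen's d", {
  # identical constant groups: degenerate, d = 0, p = 1
  res <- compare_groups(rep(5, 10), rep(5, 10))
  expect_true(res$flagged)
  expect_equal(res$cohens_d, 0)
  expect_equal(res$p, 1)

  set.seed(12)
  res <- compare_groups(rnorm(10000, 1), rnorm(10000, 0))
  expect_equal(res$cohens_d, 1, tolerance = 0.05)
  expect_equal(res$test, "welch_t")
  expect_true(res$d_lo < res$cohens_d & res$cohens_d < res$d_hi)

  # sign convention: d has the sign of mean(group1) - mean(group2)
  res2 <- compare_groups(rnorm(500, 8), rnorm(500, 10), scale = "nonnormal")
  expect_lt(res2$cohens_d, 0)
  expect_equal(res2$test, "mann_whitney_u")
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})

test_that("the empirical-logit table tracks a linear log-odds exposure", {
  n <- 20000
  set.seed(3)
  x <- rnorm(n, 9.5, 1.5)
  y <- rbinom(n, 1, plogis(-1 + 0.3 * (x - 9.5)))
  tab <- logit_linearity_table(tibble::tibble(x = x, y = y), "y", "x")
  expect_equal(nrow(tab), 10)
  slope <- coef(lm(empirical_logit ~ exposure_mid, data = tab))[2]
  expect_lt(abs(unname(slope) - 0.3), 0.05)
})
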