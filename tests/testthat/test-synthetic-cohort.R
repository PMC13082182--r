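# Synthetic cohort generator: determinism, marginal structure, causal wiring.

test_that("the same seed reproduces identical tables", {
  cfg <- sim_config(n_participants = 30, n_days = 7, seed = 42)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  for (nm in c("hr", "covariates", "genotypes", "conditions", "labs",
               "sleep", "truth", "ontology")) {
    expect_identical(s1[[nm]], s2[[nm]], label = nm)
  }
})

test_that("an SNV effect of -30 min/allele shifts mean phase by about -0.5 h", {
  cfg <- sim_config(
    n_participants = 10000, seed = 11, confounding_strength = 0,
    snv_specs = tibble::tibble(snv_id = "rs_test", ref = "C", alt = "T",
                               alt_af = 0.3, effect_min = -30)
  )
  sim <- simulate_cohort(cfg, include_hr = FALSE)
  tr <- sim$truth
  diff <- mean(tr$phase[tr$dosage_rs_test == 1]) -
    mean(tr$phase[tr$dosage_rs_test == 0])
  expect_lt(abs(diff - (-0.5)), 0.12) # ~3 SEs of the group-mean difference
})

test_that("null disease coefficients give prevalence logistic(intercept)", {
  ds <- tibble::tibble(concept_id = 500, intercept = -1.5, logor_phase = 0,
                       logor_steps = 0, logor_age = 0, logor_y = 0,
                       loghr_phase = 0, hazard_rate = 0.5)
  cfg <- sim_config(n_participants = 10000, seed = 5, disease_specs = ds)
  sim <- simulate_cohort(cfg, include_hr = FALSE)
  prev <- mean(sim$truth$disease_500)
  p0 <- plogis(-1.5)
  expect_lt(abs(prev - p0), 3 * sqrt(p0 * (1 - p0) / 10000))
})

test_that("empirical allele frequencies match configuration within 3 binomial SEs", {
  cfg <- sim_config(n_participants = 5000, seed = 9)
  sim <- simulate_cohort(cfg, include_hr = FALSE)
  af <- compute_allele_frequencies(sim$genotypes)
  for (k in seq_len(nrow(cfg$snv_specs))) {
    spec <- cfg$snv_specs[k, ]
    got <- af$alt_af[af$snv_id == spec$snv_id]
    se <- sqrt(spec$alt_af * (1 - spec$alt_af) / (2 * 5000))
    expect_lt(abs(got - spec$alt_af), 3 * se, label = spec$snv_id)
  }
})

test_that("without confounding, genotype carries no information about outcome beyond phase", {
  ds <- tibble::tibble(concept_id = 500, intercept = -2, logor_phase = 0.3,
                       logor_steps = 0, logor_age = 0, logor_y = 0,
                       loghr_phase = 0, hazard_rate = 0.5)
  cfg <- sim_config(
    n_participants = 20000, seed = 21, confounding_strength = 0,
    disease_specs = ds,
    snv_specs = tibble::tibble(snv_id = "rs_test", ref = "C", alt = "T",
                               alt_af = 0.3, effect_min = -30)
  )
  sim <- simulate_cohort(cfg, include_hr = FALSE)
  tr <- sim$truth
  fit <- glm(disease_500 ~ phase + dosage_rs_test, data = tr,
             family = binomial())
  z <- coef(summary(fit))["dosage_rs_test", "z value"]
  expect_lt(abs(z), 3)
})

test_that("toy ontology has the expected shape and is a single-rooted tree", {
  e1 <- build_toy_ontology(depth = 1, branching = 3)
  expect_equal(nrow(e1), 3)
  expect_equal(sort(unique(c(e1$parent_id, e1$child_id))), as.numeric(1:4))

  e3 <- build_toy_ontology(depth = 3, branching = 2)
  expect_equal(length(unique(c(e3$parent_id, e3$child_id))), 15)

  g <- igraph::graph_from_data_frame(
    data.frame(from = e3$parent_id, to = e3$child_id))
  expect_true(igraph::is_dag(g))
  roots <- setdiff(e3$parent_id, e3$child_id)
  expect_equal(unique(roots), 1)
  # every child reachable from the root
  d <- igraph::distances(g, v = "1", mode = "out")
  expect_true(all(is.finite(d)))
})

test_that("sleep duration is the sum of light, deep and REM, averaged over nights", {
  expect_equal(compute_sleep_duration(240, 90, 90), 420)
  expect_equal(compute_sleep_duration(0, 0, 0), 0)
  expect_error(compute_sleep_duration(-5, 10, 10), "non-negative")
  nights <- tibble::tibble(light_min = c(250, 280), deep_min = c(80, 90),
                           rem_min = c(70, 70))
  expect_equal(average_sleep_duration(nights), 420)
})

test_that("heart-rate stream degenerate cases behave", {
  cfg0 <- sim_config(n_participants = 2, n_days = 7, hr_noise_sd = 0,
                     missingness_rate = 0, seed = 3)
  sim <- simulate_cohort(cfg0, include_hr = FALSE)
  hr <- simulate_hr_stream(sim$truth, cfg0)
  fits <- extract_phases(hr)
  expect_lt(max(abs(fits$phi - (sim$truth$phase %% 24))), 1e-6)
  expect_equal(fits$r_squared, c(1, 1), tolerance = 1e-12)

  cfg1 <- sim_config(n_participants = 2, n_days = 3, missingness_rate = 1,
                     seed = 3)
  expect_equal(nrow(simulate_hr_stream(sim$truth, cfg1)), 0)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_participants = 0), "positive")
  expect_error(sim_config(snv_specs = tibble::tibble(
    snv_id = "x", ref = "A", alt = "T", alt_af = 1.2, effect_min = 0)),
    "frequencies")
  expect_error(sim_config(phase_sd = 0), "phase_sd")
})
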