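#' Simulate a complete synthetic wearable cohort
#'
#' Generates every table the analysis pipeline consumes — raw heart-rate
#' samples, participant covariates, genotypes, condition occurrences, a
#' hierarchical condition ontology, HbA1c laboratory measurements and a
#' sleep-stage table — together with a truth table holding the latent
#' quantities (true phase, dosages, confounder, latent disease status) that
#' recovery tests compare against.
#'
#' The generative chain is: genotype dosages are drawn binomially from the
#' configured allele frequencies; the true phase is
#' \deqn{\phi_i = \mu_\phi + \sum_k d_{ik}\beta_k/60 + \gamma U_i + \epsilon_i}
#' with \eqn{U_i \sim N(0,1)} an unobserved confounder and
#' \eqn{\epsilon_i \sim N(0, \sigma_\phi)}; each condition's latent case
#' status is Bernoulli with logit equal to the configured linear predictor
#' plus \eqn{\gamma U_i}; cases receive a diagnosis age of 20 years plus an
#' exponential waiting time whose rate is proportional to
#' \eqn{\exp(\beta_{HR}(\phi_i - \mu_\phi) + \gamma U_i)}, so later phase
#' means stochastically earlier diagnosis; occurrences after the censoring
#' age are unobserved. HbA1c values are linear in phase, clipped to
#' \[1, 30\]%.
#'
#' @param config A [sim_config()] object.
#' @param include_hr Generate the raw heart-rate stream (the largest table).
#'   Set `FALSE` for statistical simulations that only need the truth-level
#'   phase.
#'
#' @return A list of class `hrp_sim` with elements `hr`, `covariates`,
#'   `genotypes`, `conditions`, `ontology`, `labs`, `sleep`, `truth` and
#'   `config`. All elements are tibbles except `config`.
#' @export
simulate_cohort <- function(config = sim_config(), include_hr = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_participants
  ids <- sprintf("P%05d", seq_len(n))

  set.seed(stage_seed(config$seed, "simulate"))

  # --- covariates -----------------------------------------------------------
  age <- pmin(pmax(rnorm(n, config$age_mean, config$age_sd), 25), 85)
  y_chr <- runif(n) < config$p_y
  pcs <- matrix(rnorm(n * 5), ncol = 5, dimnames = list(NULL, PC_COLS))
  steps <- pmax(rnorm(n, config$steps_mean, config$steps_sd), 0.1)
  confounder <- rnorm(n)

  # --- genotypes ------------------------------------------------------------
  snvs <- config$snv_specs
  dosage <- sapply(seq_len(nrow(snvs)), function(k) rbinom(n, 2, snvs$alt_af[k]))
  dosage <- matrix(dosage, nrow = n)
  colnames(dosage) <- snvs$snv_id

  geno <- purrr::map_dfr(seq_len(nrow(snvs)), function(k) {
    d <- dosage[, k]
    a1 <- ifelse(d >= 1, snvs$alt[k], snvs$ref[k])
    a2 <- ifelse(d == 2, snvs$alt[k], snvs$ref[k])
    if (config$third_allele_rate > 0) {
      a1[runif(n) < config$third_allele_rate] <- "X"
      a2[runif(n) < config$third_allele_rate] <- "X"
    }
    tibble::tibble(participant_id = ids, snv_id = snvs$snv_id[k],
                   allele1 = a1, allele2 = a2)
  })

  # --- true phase -----------------------------------------------------------
  phase <- config$phase_mean +
    as.numeric(dosage %*% (snvs$effect_min / 60)) +
    config$confounding_strength * confounder +
    rnorm(n, 0, config$phase_sd)
  amplitude <- pmax(rnorm(n, config$hr_amplitude_mean, config$hr_amplitude_sd), 1)
  baseline <- rnorm(n, config$hr_baseline_mean, config$hr_baseline_sd)

  # --- ontology (toy tree + grafted disease concepts) -----------------------
  onto <- build_toy_ontology(config$ontology_depth, config$ontology_branching)
  dspecs <- config$disease_specs
  graft <- purrr::map_dfr(dspecs$concept_id, function(cid) {
    tibble::tibble(
      parent_id = c(1, cid, cid),
      child_id = c(cid, cid * 10 + 1, cid * 10 + 2)
    )
  })
  onto <- dplyr::bind_rows(onto, graft)

  # --- disease status and diagnosis ages ------------------------------------
  censor_age <- pmin(age, config$study_end_age)
  disease_cols <- list()
  cond_rows <- list()
  for (j in seq_len(nrow(dspecs))) {
    sp <- dspecs[j, ]
    lp <- sp$intercept + sp$logor_phase * phase + sp$logor_steps * steps +
      sp$logor_age * age + sp$logor_y * y_chr +
      config$confounding_strength * confounder
    latent <- runif(n) < plogis(lp)
    haz <- sp$hazard_rate *
      exp(sp$loghr_phase * (phase - config$phase_mean) +
            config$confounding_strength * confounder)
    diag_age <- 20 + rexp(n, rate = haz)
    observed <- latent & diag_age <= censor_age
    rec_id <- rep(sp$concept_id, n)
    at_desc <- runif(n) < config$record_at_descendant
    rec_id[at_desc] <- sp$concept_id * 10 + sample(1:2, n, replace = TRUE)[at_desc]
    cond_rows[[j]] <- tibble::tibble(
      participant_id = ids[observed],
      concept_id = rec_id[observed],
      age_at_occurrence = diag_age[observed]
    )
    disease_cols[[paste0("disease_", sp$concept_id)]] <- as.integer(latent)
    disease_cols[[paste0("diag_age_", sp$concept_id)]] <- diag_age
    disease_cols[[paste0("case_", sp$concept_id)]] <- as.integer(observed)
  }
  conditions <- dplyr::bind_rows(cond_rows)

  # --- HbA1c labs -----------------------------------------------------------
  start_date <- as.Date("2021-01-03") + sample(0:6, n, replace = TRUE)
  end_date <- start_date + config$n_days
  hb <- config$hba1c
  sampled <- which(runif(n) < hb$rate)
  lab_n <- sample.int(hb$max_n, length(sampled), replace = TRUE)
  labs <- tibble::tibble(
    participant_id = rep(ids[sampled], lab_n),
    idx = rep(sampled, lab_n)
  )
  labs$date <- start_date[labs$idx] +
    round(runif(nrow(labs), 0, config$n_days * 1.2))
  labs$hba1c_pct <- pmin(pmax(
    hb$mean + hb$slope_per_h * (phase[labs$idx] - config$phase_mean) +
      rnorm(nrow(labs), 0, hb$sd), 1), 30)
  labs$idx <- NULL

  # --- sleep ----------------------------------------------------------------
  sleep <- NULL
  avg_sleep <- rep(NA_real_, n)
  if (config$sleep_nights > 0) {
    nn <- config$sleep_nights
    sleep <- tibble::tibble(
      participant_id = rep(ids, each = nn),
      night = rep(seq_len(nn), times = n),
      light_min = pmax(rnorm(n * nn, 240, 30), 0),
      deep_min = pmax(rnorm(n * nn, 90, 20), 0),
      rem_min = pmax(rnorm(n * nn, 90, 20), 0)
    )
    sleep$total_min <- compute_sleep_duration(sleep$light_min, sleep$deep_min,
                                              sleep$rem_min)
    avg_sleep <- sleep |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::summarise(m = mean(.data$total_min), .groups = "drop") |>
      dplyr::pull(.data$m)
  }

  covariates <- tibble::tibble(
    participant_id = ids, age = age, y_chromosome = y_chr,
    pc1 = pcs[, 1], pc2 = pcs[, 2], pc3 = pcs[, 3], pc4 = pcs[, 4],
    pc5 = pcs[, 5], weekly_steps = steps, avg_sleep = avg_sleep,
    monitoring_start = start_date, monitoring_end = end_date
  )

  truth <- tibble::tibble(
    participant_id = ids, phase = phase, amplitude = amplitude,
    baseline = baseline, confounder = confounder,
    monitoring_start = start_date
  )
  for (k in seq_len(nrow(snvs))) {
    truth[[paste0("dosage_", snvs$snv_id[k])]] <- dosage[, k]
  }
  for (nm in names(disease_cols)) truth[[nm]] <- disease_cols[[nm]]

  hr <- NULL
  if (include_hr) {
    set.seed(stage_seed(config$seed, "hr"))
    hr <- simulate_hr_stream(truth, config)
  }

  structure(
    list(hr = hr, covariates = covariates, genotypes = geno,
         conditions = conditions, ontology = onto, labs = labs,
         sleep = sleep, truth = truth, config = config),
    class = "hrp_sim"
  )
}

#' Simulate the raw heart-rate stream for one or more participants
#'
#' Produces wearable-style heart-rate samples on a regular grid (default
#' every 5 minutes) over `config$n_days` calendar days. Each sample is
#' \deqn{A\sin(\pi/720\,(t \bmod 1440 - 60\phi)) + b + N(0, \sigma)} with
#' \eqn{t} in minutes of local wall-clock time, so the underlying rhythm has
#' a fixed 24 h (1440 min) period. Samples are dropped independently with
#' probability `config$missingness_rate`.
#'
#' @param truth One or more rows of a cohort truth table (needs columns
#'   `participant_id`, `phase`, `amplitude`, `baseline` and optionally
#'   `monitoring_start`).
#' @param config A [sim_config()].
#' @return Tibble with columns `participant_id`, `timestamp` (POSIXct, naive
#'   local time), `bpm`.
#' @export
simulate_hr_stream <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  assert_cols(truth, c("participant_id", "phase", "amplitude", "baseline"))
  n <- nrow(truth)
  start <- if ("monitoring_start" %in% names(truth)) {
    truth$monitoring_start
  } else {
    rep(as.Date("2021-01-03"), n)
  }
  grid <- seq(0, config$n_days * 1440 - config$sample_interval_min,
              by = config$sample_interval_min)
  m <- length(grid)

  idx <- rep(seq_len(n), each = m)
  t_min <- rep(grid, times = n)
  tod <- t_min %% 1440
  bpm <- truth$amplitude[idx] *
    sin(pi / 720 * (tod - 60 * truth$phase[idx])) +
    truth$baseline[idx]
  if (config$hr_noise_sd > 0) {
    bpm <- bpm + rnorm(length(bpm), 0, config$hr_noise_sd)
  }
  keep <- if (config$missingness_rate >= 1) {
    rep(FALSE, length(bpm))
  } else if (config$missingness_rate > 0) {
    runif(length(bpm)) >= config$missingness_rate
  } else {
    rep(TRUE, length(bpm))
  }
  ts <- as.POSIXct(as.numeric(as.POSIXct(start[idx], tz = "UTC")) + 60 * t_min,
                   origin = "1970-01-01", tz = "UTC")
  tibble::tibble(
    participant_id = truth$participant_id[idx][keep],
    timestamp = ts[keep],
    bpm = bpm[keep]
  )
}

#' Build a toy hierarchical condition ontology
#'
#' Constructs a complete rooted tree with deterministic integer concept ids
#' assigned breadth-first (root = 1), mimicking the shape of a hierarchical
#' clinical vocabulary.
#'
#' @param depth Number of levels below the root (>= 1).
#' @param branching Children per internal node (>= 1).
#' @return Tibble edge list with columns `parent_id`, `child_id`.
#' @examples
#' build_toy_ontology(depth = 2, branching = 2) # 7 nodes, 6 edges
#' @export
build_toy_ontology <- function(depth, branching) {
  stopifnot(depth >= 1, branching >= 1)
  parents <- integer(0)
  children <- integer(0)
  level_nodes <- 1L
  next_id <- 2L
  for (d in seq_len(depth)) {
    kids <- seq(next_id, next_id + length(level_nodes) * branching - 1L)
    parents <- c(parents, rep(level_nodes, each = branching))
    children <- c(children, kids)
    level_nodes <- kids
    next_id <- next_id + length(kids)
  }
  tibble::tibble(parent_id = as.numeric(parents),
                 child_id = as.numeric(children))
}

#' Total sleep duration from stage durations
#'
#' Total nightly sleep is the sum of light, deep and rapid-eye-movement (REM)
#' stage durations. Vectorised over nights.
#'
#' @param light,deep,rem Stage durations in minutes (non-negative).
#' @return Total sleep duration in minutes.
#' @export
compute_sleep_duration <- function(light, deep, rem) {
  if (any(c(light, deep, rem) < 0, na.rm = TRUE)) {
    stop("sleep stage durations must be non-negative", call. = FALSE)
  }
  light + deep + rem
}

#' Average sleep duration across participant-nights
#'
#' @param sleep Tibble with columns `light_min`, `deep_min`, `rem_min` (or a
#'   precomputed `total_min`).
#' @return Mean total sleep duration in minutes over all rows
#'   (participant-nights).
#' @export
average_sleep_duration <- function(sleep) {
  total <- if ("total_min" %in% names(sleep)) {
    sleep$total_min
  } else {
    compute_sleep_duration(sleep$light_min, sleep$deep_min, sleep$rem_min)
  }
  mean(total)
}

#' @export
print.hrp_sim <- function(x, ...) {
  cat("<hrp_sim> synthetic cohort\n")
  cat(sprintf("  participants: %d; HR samples: %s; conditions: %d rows\n",
              nrow(x$covariates),
              if (is.null(x$hr)) "none" else format(nrow(x$hr), big.mark = ","),
              nrow(x$conditions)))
  invisible(x)
}
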