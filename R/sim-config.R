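#' Configuration for the synthetic wearable cohort
#'
#' Collects every tunable of the synthetic-data generator into one validated
#' object. The defaults emulate the statistical structure of a large wearable
#' cohort: a 24 h heart-rate rhythm whose phase (HRP, in hours) varies across
#' participants around a morning mean, additive single-nucleotide-variant
#' (SNV) effects on phase, logistic disease risk driven by phase, activity,
#' age and sex, an exponential diagnosis-age model, and HbA1c values linked
#' linearly to phase.
#'
#' @param n_participants Number of participants to simulate.
#' @param seed Integer seed; the same seed reproduces byte-identical tables.
#' @param hr_amplitude_mean,hr_amplitude_sd Mean/SD of the sinusoid amplitude
#'   \eqn{A} (bpm). Amplitudes are truncated below at 1 bpm.
#' @param hr_baseline_mean,hr_baseline_sd Mean/SD of the vertical shift
#'   \eqn{b} (bpm).
#' @param hr_noise_sd SD of additive Gaussian noise on each 5-min heart-rate
#'   sample (bpm).
#' @param phase_mean,phase_sd Population mean and residual SD of the true
#'   phase \eqn{\phi} in hours.
#' @param snv_specs Tibble with one row per simulated variant: `snv_id`,
#'   `ref`, `alt` (allele letters), `alt_af` (alternate allele frequency in
#'   \[0,1\]) and `effect_min` (per-allele phase effect in minutes; negative =
#'   earlier phase).
#' @param disease_specs Tibble with one row per condition: `concept_id`,
#'   `intercept`, `logor_phase` (log-OR per hour of phase), `logor_steps`
#'   (log-OR per 10,000 weekly steps), `logor_age` (log-OR per year),
#'   `logor_y` (log-OR for Y-chromosome presence), `loghr_phase` (log hazard
#'   ratio per hour governing diagnosis age) and `hazard_rate` (baseline
#'   exponential rate per year from age 20).
#' @param confounding_strength Coefficient linking an unobserved standard
#'   normal confounder U to both the phase (hours per unit U) and every
#'   disease linear predictor (log-odds per unit U). 0 disables confounding.
#' @param missingness_rate Probability that any given 5-min heart-rate sample
#'   is absent.
#' @param n_days Calendar days of wearable monitoring per participant.
#' @param sample_interval_min Sampling resolution of the raw stream, minutes.
#' @param steps_mean,steps_sd Weekly step count (units of 10,000 steps/week).
#' @param age_mean,age_sd Participant age (years), truncated to \[25, 85\].
#' @param p_y Probability of carrying a Y chromosome.
#' @param hba1c List with elements `mean` (%), `sd` (%), `slope_per_h`
#'   (% change per hour of phase), `rate` (fraction of participants with any
#'   measurement) and `max_n` (max measurements per sampled participant).
#'   Values are clipped to the plausible range \[1, 30\]%.
#' @param study_end_age Administrative censoring age (years) for diagnoses.
#' @param ontology_depth,ontology_branching Shape of the toy condition
#'   ontology; disease concepts are grafted under its root with two
#'   descendants each.
#' @param record_at_descendant Probability that a condition occurrence is
#'   recorded at a descendant concept rather than the disease concept itself
#'   (exercises closure logic downstream).
#' @param third_allele_rate Probability that a genotyped allele is replaced by
#'   a third, non-ref/non-alt allele (exercises the biallelic exclusion rule).
#' @param sleep_nights Number of simulated sleep-staged nights per
#'   participant (0 disables the sleep table).
#'
#' @return A validated list of class `sim_config`.
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_participants = 1000,
                       seed = 1L,
                       hr_amplitude_mean = 10, hr_amplitude_sd = 2,
                       hr_baseline_mean = 75, hr_baseline_sd = 8,
                       hr_noise_sd = 5,
                       phase_mean = 9.48, phase_sd = 1.57,
                       snv_specs = default_snv_specs(),
                       disease_specs = default_disease_specs(),
                       confounding_strength = 0,
                       missingness_rate = 0.2,
                       n_days = 60,
                       sample_interval_min = 5,
                       steps_mean = 5.43, steps_sd = 2.49,
                       age_mean = 53.2, age_sd = 16.3,
                       p_y = 0.327,
                       hba1c = list(mean = 5.6, sd = 0.7, slope_per_h = 0.04,
                                    rate = 0.4, max_n = 3),
                       study_end_age = 75,
                       ontology_depth = 3, ontology_branching = 3,
                       record_at_descendant = 0.5,
                       third_allele_rate = 0,
                       sleep_nights = 5) {
  if (!is.numeric(n_participants) || n_participants < 1) {
    stop("n_participants must be a positive count", call. = FALSE)
  }
  if (any(snv_specs$alt_af < 0 | snv_specs$alt_af > 1)) {
    stop("allele frequencies must lie in [0, 1]", call. = FALSE)
  }
  if (phase_sd <= 0) stop("phase_sd must be > 0", call. = FALSE)
  if (n_days < 1) stop("n_days must be >= 1", call. = FALSE)
  if (missingness_rate < 0 || missingness_rate > 1) {
    stop("missingness_rate must lie in [0, 1]", call. = FALSE)
  }
  cfg <- list(
    n_participants = as.integer(n_participants), seed = as.integer(seed),
    hr_amplitude_mean = hr_amplitude_mean, hr_amplitude_sd = hr_amplitude_sd,
    hr_baseline_mean = hr_baseline_mean, hr_baseline_sd = hr_baseline_sd,
    hr_noise_sd = hr_noise_sd,
    phase_mean = phase_mean, phase_sd = phase_sd,
    snv_specs = tibble::as_tibble(snv_specs),
    disease_specs = tibble::as_tibble(disease_specs),
    confounding_strength = confounding_strength,
    missingness_rate = missingness_rate,
    n_days = as.integer(n_days),
    sample_interval_min = sample_interval_min,
    steps_mean = steps_mean, steps_sd = steps_sd,
    age_mean = age_mean, age_sd = age_sd, p_y = p_y,
    hba1c = hba1c,
    study_end_age = study_end_age,
    ontology_depth = as.integer(ontology_depth),
    ontology_branching = as.integer(ontology_branching),
    record_at_descendant = record_at_descendant,
    third_allele_rate = third_allele_rate,
    sleep_nights = as.integer(sleep_nights)
  )
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @export
default_snv_specs <- function() {
  tibble::tibble(
    snv_id = c("rs_morning1", "rs_null1", "rs_null2"),
    ref = c("C", "G", "A"),
    alt = c("T", "A", "G"),
    alt_af = c(0.025, 0.30, 0.15),
    effect_min = c(-30, 0, 0)
  )
}

#' @rdname sim_config
#' @export
default_disease_specs <- function() {
  # One T2DM-like condition (prevalence roughly 13%, OR ~1.09 per hour of
  # phase, earlier diagnosis with later phase) and one null condition.
  tibble::tibble(
    concept_id = c(201826, 900001),
    intercept = c(-3.60, -1.80),
    logor_phase = c(log(1.09), 0),
    logor_steps = c(-0.05, 0),
    logor_age = c(0.02, 0),
    logor_y = c(0.10, 0),
    loghr_phase = c(0.17, 0),
    hazard_rate = c(0.05, 0.05)
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  participants: %d, days: %d, seed: %d\n",
              x$n_participants, x$n_days, x$seed))
  cat(sprintf("  phase: %.2f +/- %.2f h; HR noise %.1f bpm; missingness %.0f%%\n",
              x$phase_mean, x$phase_sd, x$hr_noise_sd, 100 * x$missingness_rate))
  cat(sprintf("  SNVs: %d, conditions: %d, confounding: %.2f\n",
              nrow(x$snv_specs), nrow(x$disease_specs), x$confounding_strength))
  invisible(x)
}
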