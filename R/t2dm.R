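#' Flag participants with a condition via unlimited-depth closure
#'
#' A participant is flagged if they have any occurrence of the concept or of
#' any of its descendants, with no depth bound — the convention used for
#' disease-focused analyses (contrast with the depth-2 bound of the
#' phenome-wide scan).
#'
#' @param occurrences Tibble `participant_id`, `concept_id`.
#' @param ontology Edge list tibble `parent_id`, `child_id`.
#' @param concept_id Root concept (e.g. 201826 for type 2 diabetes mellitus
#'   in the OMOP vocabulary).
#' @param participants Participant universe; defaults to ids in
#'   `occurrences`.
#' @return Tibble `participant_id`, `flag` (0/1).
#' @export
flag_condition <- function(occurrences, ontology, concept_id,
                           participants = NULL) {
  closure <- descendant_closure(ontology, concept_id, max_depth = Inf)
  if (is.null(participants)) participants <- unique(occurrences$participant_id)
  hits <- occurrences |>
    dplyr::filter(.data$concept_id %in% closure) |>
    dplyr::pull(.data$participant_id) |>
    unique()
  tibble::tibble(participant_id = participants,
                 flag = as.integer(participants %in% hits))
}

#' Maximum HbA1c before the end of wearable monitoring
#'
#' Applies the plausibility range filter (1-30%) first, then takes each
#' participant's maximum HbA1c over measurements dated strictly before their
#' monitoring end date — using the maximum guards against the lowering
#' effect of anti-hyperglycaemic medication on later values. A value
#' strictly above 5.6% is considered elevated. Participants with no
#' qualifying measurement are returned with `NA` (to be excluded from HbA1c
#' models).
#'
#' @param labs Tibble `participant_id`, `date`, `hba1c_pct`.
#' @param monitoring_end Tibble `participant_id`, `monitoring_end` (Date).
#' @param range Inclusive plausibility range (default `c(1, 30)`).
#' @param elevated_threshold Strict threshold for the elevated flag
#'   (default 5.6).
#' @return Tibble `participant_id`, `max_hba1c`, `elevated` (NA when no
#'   qualifying measurement).
#' @export
max_hba1c_before_end <- function(labs, monitoring_end, range = c(1, 30),
                                 elevated_threshold = 5.6) {
  assert_cols(labs, c("participant_id", "date", "hba1c_pct"))
  assert_cols(monitoring_end, c("participant_id", "monitoring_end"))
  qual <- labs |>
    dplyr::filter(.data$hba1c_pct >= range[1], .data$hba1c_pct <= range[2]) |>
    dplyr::inner_join(monitoring_end, by = "participant_id") |>
    dplyr::filter(.data$date < .data$monitoring_end) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(max_hba1c = suppressWarnings(max(.data$hba1c_pct)),
                     .groups = "drop") |>
    dplyr::filter(is.finite(.data$max_hba1c))
  monitoring_end |>
    dplyr::select("participant_id") |>
    dplyr::left_join(qual, by = "participant_id") |>
    dplyr::mutate(elevated = .data$max_hba1c > elevated_threshold)
}

#' Logistic disease-risk model with robust standard errors
#'
#' Regresses a binary outcome on a single exposure (heart-rate phase in
#' hours, or an additive genotype dosage) plus adjustment covariates, with
#' sandwich robust standard errors, reporting the odds ratio per unit of
#' exposure with a 95% CI.
#'
#' @param data Analysis tibble containing the outcome, exposure and
#'   covariates.
#' @param outcome,exposure Column names.
#' @param covariates Adjustment covariate names (default weekly steps, age,
#'   Y flag, pc1-5).
#' @param hc_type Sandwich flavour (default `"HC1"`).
#' @return One-row tibble: `exposure`, `beta`, `se`, `or`, `or_lo`, `or_hi`,
#'   `p`, `n`, `n_cases`, `converged`.
#' @export
logistic_risk <- function(data, outcome, exposure,
                          covariates = c("weekly_steps", DEFAULT_COVARS),
                          hc_type = "HC1") {
  assert_cols(data, c(outcome, exposure, covariates))
  df <- data[complete.cases(data[, c(outcome, exposure, covariates)]), ]
  y <- df[[outcome]]
  if (length(unique(y)) < 2) stop("outcome does not vary", call. = FALSE)
  rhs <- paste(c(exposure, covariates), collapse = " + ")
  f <- as.formula(paste(outcome, "~", rhs))
  fit <- suppressWarnings(glm(f, data = df, family = binomial()))
  sep <- any(fitted(fit) > 1 - 1e-10) || any(fitted(fit) < 1e-10)
  converged <- fit$converged && !sep && !anyNA(coef(fit))
  if (!converged) {
    return(tibble::tibble(exposure = exposure, beta = NA_real_, se = NA_real_,
                          or = NA_real_, or_lo = NA_real_, or_hi = NA_real_,
                          p = NA_real_, n = nrow(df), n_cases = sum(y),
                          converged = FALSE))
  }
  rc <- robust_coefs(fit, hc_type)
  row <- rc[rc$term == exposure, ]
  z <- row$estimate / row$std_error
  tibble::tibble(
    exposure = exposure, beta = row$estimate, se = row$std_error,
    or = exp(row$estimate),
    or_lo = exp(row$estimate - qnorm(0.975) * row$std_error),
    or_hi = exp(row$estimate + qnorm(0.975) * row$std_error),
    p = 2 * pnorm(-abs(z)), n = nrow(df), n_cases = sum(y), converged = TRUE
  )
}

#' Empirical-logit linearity diagnostic
#'
#' Splits the exposure into quantile bins and tabulates the empirical log
#' odds of the outcome per bin — a tabular check that the log odds are
#' roughly linear in the exposure.
#'
#' @param data,outcome,exposure As in [logistic_risk()].
#' @param n_bins Number of quantile bins (default 10, i.e. deciles).
#' @return Tibble `bin`, `exposure_mid`, `n`, `n_cases`, `empirical_logit`
#'   (with a 0.5 continuity correction).
#' @export
logit_linearity_table <- function(data, outcome, exposure, n_bins = 10) {
  x <- data[[exposure]]
  y <- data[[outcome]]
  br <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                        na.rm = TRUE))
  bin <- cut(x, breaks = br, include.lowest = TRUE)
  tibble::tibble(bin = bin, x = x, y = y) |>
    dplyr::filter(!is.na(.data$bin)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(exposure_mid = mean(.data$x), n = dplyr::n(),
                     n_cases = sum(.data$y),
                     empirical_logit = log((.data$n_cases + 0.5) /
                                             (.data$n - .data$n_cases + 0.5)),
                     .groups = "drop")
}

#' Build survival records for age-at-diagnosis analysis
#'
#' Event age is the earliest occurrence of the concept or any descendant
#' (unlimited closure); participants without an event are right censored at
#' the lesser of age at death and age at the end of the study period.
#'
#' @param cohort Cohort tibble with `participant_id`, covariates, `age`
#'   (interpreted as age at study end) and optionally `age_at_death`,
#'   `monitoring_start_age` (age at first wearable sample, used by the
#'   post-monitoring subgroup filter).
#' @param occurrences,ontology,concept_id As in [flag_condition()].
#' @return Cohort tibble plus `event` (0/1) and `age_at_event_or_censor`.
#' @export
build_survival_records <- function(cohort, occurrences, ontology, concept_id) {
  closure <- descendant_closure(ontology, concept_id, max_depth = Inf)
  first_diag <- occurrences |>
    dplyr::filter(.data$concept_id %in% closure) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(diag_age = min(.data$age_at_occurrence), .groups = "drop")
  censor <- if ("age_at_death" %in% names(cohort)) {
    pmin(cohort$age, cohort$age_at_death, na.rm = TRUE)
  } else {
    cohort$age
  }
  out <- cohort |>
    dplyr::left_join(first_diag, by = "participant_id") |>
    dplyr::mutate(censor_age = censor,
                  event = as.integer(!is.na(.data$diag_age) &
                                       .data$diag_age <= .data$censor_age),
                  age_at_event_or_censor = ifelse(.data$event == 1,
                                                  .data$diag_age,
                                                  .data$censor_age))
  out
}

#' Sex-stratified Cox proportional hazards on the age scale
#'
#' Partial-likelihood Cox regression of age at diagnosis on an exposure,
#' stratified by Y-chromosome presence to satisfy the proportional-hazards
#' assumption, with weekly steps and the five ancestry principal components
#' as covariates. The proportional-hazards assumption is checked via
#' scaled-Schoenfeld residuals ([survival::cox.zph()]) and the exposure's
#' global test p-value reported. The subgroup option restricts to
#' participants whose first diagnosis postdates the start of wearable
#' monitoring (undiagnosed participants are kept).
#'
#' @param records Output of [build_survival_records()] (needs `event`,
#'   `age_at_event_or_censor`, the exposure, covariates and the stratum
#'   column; `monitoring_start_age` for the subgroup filter).
#' @param exposure Exposure column (phase in hours or genotype dosage).
#' @param covariates Covariates (default weekly steps + pc1-5; age is the
#'   timescale, not a covariate).
#' @param stratum Stratification column (default `y_chromosome`).
#' @param subgroup `"all"` or `"post_monitoring"`.
#' @return One-row tibble: `exposure`, `loghr`, `se`, `hr`, `hr_lo`,
#'   `hr_hi`, `p`, `n`, `n_events`, `ph_p` (scaled-Schoenfeld test for the
#'   exposure), `ph_ok`.
#' @export
cox_age_at_diagnosis <- function(records, exposure,
                                 covariates = c("weekly_steps", PC_COLS),
                                 stratum = "y_chromosome",
                                 subgroup = c("all", "post_monitoring")) {
  subgroup <- match.arg(subgroup)
  assert_cols(records, c("event", "age_at_event_or_censor", exposure,
                         covariates, stratum))
  df <- records
  if (subgroup == "post_monitoring") {
    assert_cols(df, "monitoring_start_age")
    keep <- df$event == 0 |
      (!is.na(df$age_at_event_or_censor) &
         df$age_at_event_or_censor > df$monitoring_start_age)
    df <- df[keep, ]
  }
  df <- df[complete.cases(df[, c("event", "age_at_event_or_censor", exposure,
                                 covariates, stratum)]), ]
  if (sum(df$event) == 0) stop("no events in the analysis set", call. = FALSE)
  f <- as.formula(paste(
    "survival::Surv(age_at_event_or_censor, event) ~", exposure, "+",
    paste(covariates, collapse = " + "), "+ survival::strata(", stratum, ")"))
  fit <- survival::coxph(f, data = df)
  sm <- summary(fit)
  est <- sm$coefficients[exposure, "coef"]
  se <- sm$coefficients[exposure, "se(coef)"]
  zph <- tryCatch(survival::cox.zph(fit), error = function(e) NULL)
  ph_p <- if (!is.null(zph) && exposure %in% rownames(zph$table)) {
    zph$table[exposure, "p"]
  } else {
    NA_real_
  }
  tibble::tibble(
    exposure = exposure, loghr = est, se = se, hr = exp(est),
    hr_lo = exp(est - qnorm(0.975) * se), hr_hi = exp(est + qnorm(0.975) * se),
    p = sm$coefficients[exposure, "Pr(>|z|)"],
    n = nrow(df), n_events = sum(df$event),
    ph_p = ph_p, ph_ok = is.na(ph_p) | ph_p > 0.05
  )
}

#' Two-group comparison with effect size
#'
#' Welch's unequal-variance t test for normally distributed data or the
#' Mann-Whitney U test otherwise, plus Cohen's d (pooled-SD definition,
#' sign = group1 - group2) with a 95% CI from the large-sample normal
#' approximation to the standard error of d.
#'
#' @param x,y Numeric value vectors for the two groups (each length >= 2).
#' @param scale `"normal"` (Welch) or `"nonnormal"` (Mann-Whitney).
#' @return One-row tibble: `test`, `p`, `cohens_d`, `d_lo`, `d_hi`, `n1`,
#'   `n2`, `flagged` (degenerate input: zero variance in both groups).
#' @export
compare_groups <- function(x, y, scale = c("normal", "nonnormal")) {
  scale <- match.arg(scale)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("both groups need at least 2 values", call. = FALSE)
  }
  n1 <- length(x); n2 <- length(y)
  s_pooled2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  degenerate <- s_pooled2 <= 0
  d <- if (degenerate && mean(x) == mean(y)) {
    0
  } else if (degenerate) {
    NA_real_
  } else {
    (mean(x) - mean(y)) / sqrt(s_pooled2)
  }
  se_d <- if (degenerate) NA_real_ else {
    sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  }
  p <- if (degenerate) {
    1
  } else if (scale == "normal") {
    t.test(x, y)$p.value
  } else {
    suppressWarnings(wilcox.test(x, y)$p.value)
  }
  tibble::tibble(
    test = if (scale == "normal") "welch_t" else "mann_whitney_u",
    p = p, cohens_d = d,
    d_lo = d - qnorm(0.975) * se_d, d_hi = d + qnorm(0.975) * se_d,
    n1 = n1, n2 = n2, flagged = degenerate
  )
}
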