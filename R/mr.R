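#' One-sample Mendelian randomization by two-stage residual inclusion
#'
#' Estimates the causal effect of an exposure (heart-rate phase, hours) on a
#' binary outcome using a genetic instrument, by two-stage residual
#' inclusion (2SRI). Stage 1 regresses the exposure on the instrument
#' (additive dosage) and the exogenous covariates by ordinary least squares;
#' the instrument's strength is summarised by the Wald F statistic of its
#' coefficient and the stage-1 model \eqn{R^2}. Stage 2 is a logistic
#' regression of the outcome on the stage-1 residual, the exposure and the
#' exogenous covariates; the causal estimate is the stage-2 exposure
#' coefficient (log-odds per hour), while the residual coefficient is an
#' endogeneity diagnostic. Confidence intervals are percentile intervals
#' from a participant-level bootstrap in which both stages are re-fit in
#' every resample; both the bootstrap and the analytic (stage-2 Wald)
#' p-value are reported, the bootstrap p with the standard +1 correction.
#'
#' An instrument F below 10 triggers a weak-instrument warning (the fit is
#' still returned). Non-convergent bootstrap replicates are dropped and
#' counted.
#'
#' @param data Analysis tibble.
#' @param outcome Binary outcome column (e.g. T2DM flag or elevated HbA1c).
#' @param instrument Additive genotype dosage column.
#' @param exposure Exposure column (default `"phi"`).
#' @param exogenous Exogenous covariate names (default weekly steps, age, Y
#'   flag, pc1-5).
#' @param n_resamples Bootstrap resamples (default 100,000; scale down for
#'   exploratory runs).
#' @param seed Seed for the bootstrap; fixed seed and `n_resamples` give an
#'   identical CI.
#' @param ci_level Confidence level (default 0.95).
#' @return Object of class `hrp_mr`; see [tidy.hrp_mr()] and
#'   [glance.hrp_mr()].
#' @export
mr_2sri <- function(data, outcome, instrument, exposure = "phi",
                    exogenous = c("weekly_steps", DEFAULT_COVARS),
                    n_resamples = 100000, seed = NULL, ci_level = 0.95) {
  assert_cols(data, c(outcome, instrument, exposure, exogenous))
  df <- data[complete.cases(data[, c(outcome, instrument, exposure,
                                     exogenous)]), ]
  n <- nrow(df)
  y <- as.numeric(df[[outcome]])
  if (length(unique(y)) < 2) stop("outcome does not vary", call. = FALSE)
  if (length(unique(df[[instrument]])) < 2) {
    stop("instrument does not vary", call. = FALSE)
  }

  exog <- as.matrix(df[, exogenous])
  storage.mode(exog) <- "double"
  X1 <- cbind(`(Intercept)` = 1, iv = as.numeric(df[[instrument]]), exog)
  xvar <- as.numeric(df[[exposure]])

  # Stage 1: OLS of exposure on instrument + exogenous
  qr1 <- qr(X1)
  cf1 <- qr.coef(qr1, xvar)
  res1 <- xvar - X1 %*% cf1
  rss <- sum(res1^2)
  tss <- sum((xvar - mean(xvar))^2)
  r2 <- 1 - rss / tss
  sigma2 <- rss / (n - ncol(X1))
  XtXinv <- chol2inv(qr.R(qr1))
  se_iv <- sqrt(sigma2 * XtXinv[2, 2])
  F_iv <- (cf1[["iv"]] / se_iv)^2

  # Stage 2: logistic of outcome on stage-1 residual + exposure + exogenous
  X2 <- cbind(`(Intercept)` = 1, resid1 = as.numeric(res1), exposure = xvar,
              exog)
  fit2 <- suppressWarnings(glm.fit(X2, y, family = binomial()))
  cf2 <- fit2$coefficients
  # analytic covariance from the IRLS weights
  W <- fit2$weights
  V <- chol2inv(chol(crossprod(X2 * sqrt(W))))
  se2 <- sqrt(diag(V))
  z_exp <- cf2[["exposure"]] / se2[3]
  z_res <- cf2[["resid1"]] / se2[2]

  # Naive (non-instrumented) logistic fit for comparison
  Xn <- cbind(1, exposure = xvar, exog)
  cfn <- fast_logit_coef(Xn, y)

  # Participant-level bootstrap of both stages
  boot <- rep(NA_real_, n_resamples)
  if (n_resamples > 0) {
    if (!is.null(seed)) set.seed(seed)
    for (b in seq_len(n_resamples)) {
      idx <- sample.int(n, n, replace = TRUE)
      X1b <- X1[idx, , drop = FALSE]
      xb <- xvar[idx]
      f1 <- .lm.fit(X1b, xb)
      X2b <- cbind(X2[idx, 1, drop = FALSE], f1$residuals, xb,
                   exog[idx, , drop = FALSE])
      cfb <- irls_logit(X2b, y[idx], start = cf2)
      if (!is.null(cfb)) boot[b] <- cfb[3]
    }
  }
  ok <- boot[is.finite(boot)]
  n_dropped <- n_resamples - length(ok)
  alpha <- 1 - ci_level
  ci <- if (length(ok) > 1) {
    unname(quantile(ok, c(alpha / 2, 1 - alpha / 2), type = 7))
  } else {
    c(NA_real_, NA_real_)
  }
  p_boot <- if (length(ok) > 1) {
    2 * min((sum(ok <= 0) + 1) / (length(ok) + 1),
            (sum(ok >= 0) + 1) / (length(ok) + 1))
  } else {
    NA_real_
  }

  weak <- F_iv < 10
  if (weak) {
    warning(sprintf("weak instrument: stage-1 F = %.2f (< 10)", F_iv),
            call. = FALSE)
  }

  structure(list(
    stage1_beta_iv = unname(cf1[["iv"]]), stage1_se_iv = se_iv,
    stage1_F = unname(F_iv), stage1_r_squared = r2,
    stage2_beta = unname(cf2[["exposure"]]), stage2_se = se2[3],
    p_analytic = 2 * pnorm(-abs(z_exp)),
    residual_beta = unname(cf2[["resid1"]]),
    residual_p = 2 * pnorm(-abs(z_res)),
    naive_beta = unname(cfn[["exposure"]]),
    ci_lo = ci[1], ci_hi = ci[2], p_boot = p_boot,
    boot_se = if (length(ok) > 1) sd(ok) else NA_real_,
    n = n, n_resamples = n_resamples, n_dropped = n_dropped,
    seed = seed, weak_instrument = weak,
    outcome = outcome, instrument = instrument, exposure = exposure
  ), class = "hrp_mr")
}

#' @export
print.hrp_mr <- function(x, ...) {
  cat("<hrp_mr> one-sample MR, two-stage residual inclusion\n")
  cat(sprintf("  stage 1: F = %.2f, R^2 = %.3f (instrument %s)%s\n",
              x$stage1_F, x$stage1_r_squared, x$instrument,
              if (x$weak_instrument) " [WEAK]" else ""))
  cat(sprintf("  stage 2: log-OR(%s) = %.4f per unit, 95%% CI [%.4f, %.4f]\n",
              x$exposure, x$stage2_beta, x$ci_lo, x$ci_hi))
  cat(sprintf("  p (analytic) = %.3g, p (bootstrap, %d resamples) = %.3g\n",
              x$p_analytic, x$n_resamples, x$p_boot))
  invisible(x)
}

#' Tidy a 2SRI Mendelian randomization fit
#'
#' @param x An `hrp_mr` object.
#' @param ... Unused.
#' @return Tibble with one row per reported term (stage-2 exposure, stage-2
#'   residual diagnostic, stage-1 instrument).
#' @export
tidy.hrp_mr <- function(x, ...) {
  tibble::tibble(
    term = c("exposure (2SRI)", "stage1 residual", "instrument (stage 1)"),
    estimate = c(x$stage2_beta, x$residual_beta, x$stage1_beta_iv),
    std_error = c(x$stage2_se, NA_real_, x$stage1_se_iv),
    conf_low = c(x$ci_lo, NA_real_, NA_real_),
    conf_high = c(x$ci_hi, NA_real_, NA_real_),
    p_value = c(x$p_analytic, x$residual_p, NA_real_)
  )
}

#' Glance at a 2SRI Mendelian randomization fit
#'
#' @param x An `hrp_mr` object.
#' @param ... Unused.
#' @return One-row tibble of fit-level diagnostics.
#' @export
glance.hrp_mr <- function(x, ...) {
  tibble::tibble(
    stage1_F = x$stage1_F, stage1_r_squared = x$stage1_r_squared,
    stage2_beta = x$stage2_beta, ci_lo = x$ci_lo, ci_hi = x$ci_hi,
    p_analytic = x$p_analytic, p_boot = x$p_boot, naive_beta = x$naive_beta,
    n = x$n, n_resamples = x$n_resamples, n_dropped = x$n_dropped,
    weak_instrument = x$weak_instrument
  )
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
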