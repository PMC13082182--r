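# Internal helpers shared across modules.

# Wrap a phase (hours) into [0, 24).
wrap24 <- function(phi) {
  out <- phi %% 24
  out[out == 24] <- 0
  out
}

# Deterministic per-stage sub-seed derived from a single run seed.
# Keeps results independent across stages while reproducible end to end.
stage_seed <- function(seed, stage) {
  offsets <- c(
    simulate = 101L, hr = 211L, phase = 307L, genetics = 401L,
    phewas = 503L, t2dm = 601L, mr = 701L, boot = 809L
  )
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 1009 + off) %% 2147483647)
}

# Fast weighted-free OLS via QR; returns coefficients only.
fast_ols_coef <- function(X, y) {
  fit <- .lm.fit(X, y)
  cf <- fit$coefficients
  names(cf) <- colnames(X)
  cf
}

# Fast logistic fit via glm.fit; returns coefficients (NA on failure).
fast_logit_coef <- function(X, y) {
  fit <- tryCatch(
    suppressWarnings(glm.fit(X, y, family = binomial())),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$converged) {
    return(setNames(rep(NA_real_, ncol(X)), colnames(X)))
  }
  cf <- fit$coefficients
  names(cf) <- colnames(X)
  cf
}

#' @importFrom stats glm.fit .lm.fit
NULL

# Minimal IRLS for logistic regression, used inside tight bootstrap loops.
# Same estimator as glm.fit(binomial), much less per-call overhead.
# Returns coefficient vector or NULL if not converged.
irls_logit <- function(X, y, start, maxit = 30, tol = 1e-8) {
  beta <- start
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    eta <- pmin(pmax(eta, -30), 30)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    sw <- sqrt(w)
    fit <- tryCatch(.lm.fit(X * sw, z * sw), error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    beta_new <- fit$coefficients
    if (anyNA(beta_new)) return(NULL)
    if (max(abs(beta_new - beta)) < tol * (1 + max(abs(beta)))) {
      return(beta_new)
    }
    beta <- beta_new
  }
  NULL
}

# Robust (sandwich) coefficient table for an lm/glm fit.
robust_coefs <- function(fit, hc_type = "HC1") {
  ct <- lmtest::coeftest(fit, vcov. = sandwich::vcovHC(fit, type = hc_type))
  tibble::tibble(
    term = rownames(ct),
    estimate = unname(ct[, "Estimate"]),
    std_error = unname(ct[, "Std. Error"]),
    statistic = unname(ct[, 3]),
    p_value = unname(ct[, 4])
  )
}

# Bonferroni adjustment: p * m capped at 1.
bonferroni <- function(p, m = length(p)) pmin(1, p * m)

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
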