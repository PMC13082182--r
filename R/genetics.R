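#' Allele frequencies and biallelic coding for single-nucleotide variants
#'
#' Counts alleles per SNV over a long-format genotype table (two alleles per
#' participant, diploid autosomal assumption). The reference (non-effect)
#' allele is the most frequent allele, the alternate (effect) allele the
#' second most frequent; ties are broken alphabetically for determinism.
#' Variants whose alternate allele frequency falls below `min_af` are flagged
#' excluded, as are monomorphic variants (alt AF 0).
#'
#' @param genotypes Long tibble: `participant_id`, `snv_id`, `allele1`,
#'   `allele2`.
#' @param min_af Minimum alternate allele frequency for retention
#'   (default 0.01).
#' @return Tibble per SNV: `snv_id`, `ref`, `alt`, `ref_af`, `alt_af`,
#'   `n_alleles` (chromosomes counted), `n_other` (alleles beyond the top
#'   two), `excluded`.
#' @export
compute_allele_frequencies <- function(genotypes, min_af = 0.01) {
  assert_cols(genotypes, c("participant_id", "snv_id", "allele1", "allele2"))
  long <- tibble::tibble(
    snv_id = rep(genotypes$snv_id, 2),
    allele = c(genotypes$allele1, genotypes$allele2)
  )
  long |>
    dplyr::count(.data$snv_id, .data$allele, name = "n") |>
    dplyr::arrange(.data$snv_id, dplyr::desc(.data$n), .data$allele) |>
    dplyr::group_by(.data$snv_id) |>
    dplyr::summarise(
      ref = .data$allele[1],
      alt = ifelse(dplyr::n() >= 2, .data$allele[2], NA_character_),
      ref_af = .data$n[1] / sum(.data$n),
      alt_af = ifelse(dplyr::n() >= 2, .data$n[2] / sum(.data$n), 0),
      n_alleles = sum(.data$n),
      n_other = sum(.data$n[-(1:2)]),
      .groups = "drop"
    ) |>
    dplyr::mutate(excluded = .data$alt_af < min_af)
}

#' Additive genotype coding
#'
#' Codes each participant's genotype as the number of copies of the
#' alternate allele (dosage 0/1/2). Participants carrying any allele other
#' than the SNV's reference or alternate allele receive `NA` and are thereby
#' excluded from that SNV's analysis; AF-excluded SNVs are dropped entirely.
#'
#' @param genotypes Long genotype tibble (see
#'   [compute_allele_frequencies()]).
#' @param snv_table Output of [compute_allele_frequencies()].
#' @return Tibble `participant_id`, `snv_id`, `dosage`.
#' @export
code_additive <- function(genotypes, snv_table) {
  keep <- snv_table |> dplyr::filter(!.data$excluded)
  genotypes |>
    dplyr::inner_join(keep |> dplyr::select("snv_id", "ref", "alt"),
                      by = "snv_id") |>
    dplyr::mutate(
      ok = .data$allele1 %in% c(.data$ref, .data$alt) &
        .data$allele2 %in% c(.data$ref, .data$alt),
      dosage = ifelse(.data$ok,
                      (.data$allele1 == .data$alt) + (.data$allele2 == .data$alt),
                      NA_integer_)
    ) |>
    dplyr::select("participant_id", "snv_id", "dosage")
}

#' Genotype-phase association scan
#'
#' For each SNV, heart-rate phase (hours) is regressed by ordinary least
#' squares on additive dosage, age, Y-chromosome presence and the first five
#' genomic-ancestry principal components. Standard errors are
#' heteroskedasticity-consistent (sandwich; HC1 by default) and two-sided
#' p-values come from the robust z statistic. Effects are reported in
#' minutes of phase per alternate allele; a negative effect means the allele
#' shifts phase earlier (morningness). P-values are Bonferroni-adjusted for
#' the number of SNVs actually tested in the call.
#'
#' @param cohort Included-cohort tibble with `participant_id`, `phi` and the
#'   adjustment covariates.
#' @param dosages Output of [code_additive()].
#' @param covariates Adjustment covariate names (default age, Y flag, pc1-5).
#' @param hc_type Sandwich flavour, one of `"HC0"`-`"HC3"` (default HC1).
#' @return Tibble of class `hrp_assoc`: `snv_id`, `beta_min` (minutes per
#'   allele), `se_min`, `p`, `p_adj`, `n`, `converged`.
#' @export
associate_snv_phase <- function(cohort, dosages,
                                covariates = DEFAULT_COVARS,
                                hc_type = "HC1") {
  assert_cols(cohort, c("participant_id", "phi", covariates))
  snv_ids <- unique(dosages$snv_id)
  res <- purrr::map_dfr(snv_ids, function(sid) {
    d <- dosages |>
      dplyr::filter(.data$snv_id == sid, !is.na(.data$dosage)) |>
      dplyr::select("participant_id", "dosage")
    df <- dplyr::inner_join(
      cohort |> dplyr::select(!dplyr::any_of("dosage")), d,
      by = "participant_id")
    df <- df[complete.cases(df[, c("phi", "dosage", covariates)]), ]
    if (nrow(df) < 3 || length(unique(df$dosage)) < 2) {
      return(tibble::tibble(snv_id = sid, beta_min = NA_real_,
                            se_min = NA_real_, p = NA_real_, n = nrow(df),
                            converged = FALSE))
    }
    f <- as.formula(paste("phi ~ dosage +", paste(covariates, collapse = " + ")))
    fit <- lm(f, data = df)
    if (anyNA(coef(fit))) {
      return(tibble::tibble(snv_id = sid, beta_min = NA_real_,
                            se_min = NA_real_, p = NA_real_, n = nrow(df),
                            converged = FALSE))
    }
    rc <- robust_coefs(fit, hc_type)
    row <- rc[rc$term == "dosage", ]
    tibble::tibble(snv_id = sid, beta_min = 60 * row$estimate,
                   se_min = 60 * row$std_error,
                   p = 2 * pnorm(-abs(row$estimate / row$std_error)),
                   n = nrow(df), converged = TRUE)
  })
  m <- sum(!is.na(res$p))
  res$p_adj <- bonferroni(res$p, m)
  res <- res |> dplyr::relocate("p_adj", .after = "p")
  class(res) <- c("hrp_assoc", class(res))
  res
}
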