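#' Bounded descendant closure over a condition ontology
#'
#' Returns the concept itself plus every concept reachable along
#' parent-to-child edges within `max_depth` steps (shortest-path distance,
#' so the ontology may be a DAG). Ordering is deterministic: by distance,
#' then by concept id.
#'
#' @param ontology Edge list tibble: `parent_id`, `child_id`.
#' @param concept Concept id present in the ontology.
#' @param max_depth Maximum graph distance below the concept; `Inf` for the
#'   unlimited closure used in disease-focused analyses (default 2, the
#'   phenome-wide convention).
#' @return Vector of concept ids (same type as the ontology columns).
#' @export
descendant_closure <- function(ontology, concept, max_depth = 2) {
  assert_cols(ontology, c("parent_id", "child_id"))
  nodes <- unique(c(ontology$parent_id, ontology$child_id))
  if (!concept %in% nodes) {
    stop(sprintf("concept %s not present in ontology", concept), call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(ontology$parent_id),
               to = as.character(ontology$child_id)),
    directed = TRUE
  )
  d <- igraph::distances(g, v = as.character(concept), mode = "out")[1, ]
  keep <- names(d)[is.finite(d) & d <= max_depth]
  ord <- order(d[keep], suppressWarnings(as.numeric(keep)), keep)
  ids <- keep[ord]
  if (is.numeric(ontology$parent_id)) as.numeric(ids) else ids
}

# Distance matrix from every ontology node, for batch closure computation.
ontology_distances <- function(ontology) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(ontology$parent_id),
               to = as.character(ontology$child_id)),
    directed = TRUE
  )
  list(graph = g, dist = igraph::distances(g, mode = "out"))
}

#' Build the participant-by-condition phenotype matrix
#'
#' A participant is a case for a concept if they have an occurrence of the
#' concept itself or of any descendant within `max_depth` degrees of
#' separation. Concepts with case counts of `min_cases` or fewer are dropped
#' (strictly more than `min_cases` cases are required, so a concept with
#' exactly `min_cases` cases is excluded).
#'
#' @param occurrences Tibble `participant_id`, `concept_id` (and optionally
#'   `age_at_occurrence`).
#' @param ontology Edge list tibble `parent_id`, `child_id`.
#' @param participants Participant universe (ids); defaults to those in
#'   `occurrences`. Case counts are computed within this universe.
#' @param concepts Concepts to evaluate; defaults to every ontology node.
#' @param max_depth Closure depth bound (default 2).
#' @param min_cases Strict lower bound on case counts (default 100).
#' @return List of class `hrp_phenotype_matrix`: `cases` (long tibble of
#'   participant-concept case pairs for retained concepts), `concepts`
#'   (per-concept `n_cases`, `retained`), `participants`, `max_depth`,
#'   `min_cases`.
#' @export
build_phenotype_matrix <- function(occurrences, ontology,
                                   participants = NULL, concepts = NULL,
                                   max_depth = 2, min_cases = 100) {
  assert_cols(occurrences, c("participant_id", "concept_id"))
  nodes <- unique(c(ontology$parent_id, ontology$child_id))
  unknown <- setdiff(unique(occurrences$concept_id), nodes)
  if (length(unknown)) {
    stop(sprintf("occurrences reference unknown concept(s): %s",
                 paste(head(unknown, 5), collapse = ", ")), call. = FALSE)
  }
  if (is.null(participants)) participants <- unique(occurrences$participant_id)
  if (is.null(concepts)) concepts <- sort(nodes)
  occ <- occurrences |>
    dplyr::filter(.data$participant_id %in% participants) |>
    dplyr::distinct(.data$participant_id, .data$concept_id)

  od <- ontology_distances(ontology)
  dmat <- od$dist
  cases <- purrr::map_dfr(concepts, function(cid) {
    key <- as.character(cid)
    drow <- dmat[key, ]
    closure <- names(drow)[is.finite(drow) & drow <= max_depth]
    closure <- if (is.numeric(occ$concept_id)) as.numeric(closure) else closure
    hit <- occ |> dplyr::filter(.data$concept_id %in% closure)
    tibble::tibble(participant_id = unique(hit$participant_id),
                   concept_id = cid)
  })
  counts <- cases |>
    dplyr::count(.data$concept_id, name = "n_cases") |>
    dplyr::right_join(tibble::tibble(concept_id = concepts), by = "concept_id") |>
    dplyr::mutate(n_cases = dplyr::coalesce(.data$n_cases, 0L),
                  retained = .data$n_cases > min_cases) |>
    dplyr::arrange(.data$concept_id)
  structure(
    list(cases = cases |>
           dplyr::semi_join(counts |> dplyr::filter(.data$retained),
                            by = "concept_id"),
         concepts = counts, participants = participants,
         max_depth = max_depth, min_cases = min_cases),
    class = "hrp_phenotype_matrix"
  )
}

#' @export
print.hrp_phenotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<hrp_phenotype_matrix> %d participants, %d/%d concepts retained (> %d cases), depth <= %s\n",
    length(x$participants), sum(x$concepts$retained), nrow(x$concepts),
    x$min_cases, format(x$max_depth)))
  invisible(x)
}

#' Phenome-wide association of heart-rate phase with conditions
#'
#' Fits one logistic regression per retained concept: case status as a
#' function of phase (hours), weekly steps, age, sex (Y-chromosome presence)
#' and the first five ancestry principal components, with sandwich (HC1)
#' robust standard errors. Reports the odds ratio per hour of phase with a
#' 95% CI and Bonferroni adjustment over the number of retained concepts.
#' Concepts whose fit does not converge or shows complete separation are
#' flagged, not dropped.
#'
#' @param cohort Included-cohort tibble (`participant_id`, `phi`, covariates).
#' @param pheno A [build_phenotype_matrix()] result.
#' @param covariates Adjustment covariates (default weekly steps, age, Y
#'   flag, pc1-5).
#' @param hc_type Sandwich flavour (default `"HC1"`).
#' @return Tibble of class `hrp_phewas`: `concept_id`, `n_cases`, `beta`
#'   (log-odds per hour), `se`, `or`, `or_lo`, `or_hi`, `p`, `p_adj`,
#'   `converged`, sorted by `p`.
#' @export
run_phewas <- function(cohort, pheno,
                       covariates = c("weekly_steps", DEFAULT_COVARS),
                       hc_type = "HC1") {
  stopifnot(inherits(pheno, "hrp_phenotype_matrix"))
  assert_cols(cohort, c("participant_id", "phi", covariates))
  retained <- pheno$concepts |> dplyr::filter(.data$retained)
  if (nrow(retained) == 0) {
    out <- tibble::tibble(concept_id = numeric(0), n_cases = integer(0),
                          beta = numeric(0), se = numeric(0), or = numeric(0),
                          or_lo = numeric(0), or_hi = numeric(0),
                          p = numeric(0), p_adj = numeric(0),
                          converged = logical(0))
    class(out) <- c("hrp_phewas", class(out))
    return(out)
  }
  df0 <- cohort[complete.cases(cohort[, c("phi", covariates)]), ]
  f <- as.formula(paste("y ~ phi +", paste(covariates, collapse = " + ")))
  res <- purrr::map_dfr(retained$concept_id, function(cid) {
    case_ids <- pheno$cases$participant_id[pheno$cases$concept_id == cid]
    df <- df0
    df$y <- as.integer(df$participant_id %in% case_ids)
    nc <- sum(df$y)
    if (nc == 0 || nc == nrow(df)) {
      return(tibble::tibble(concept_id = cid, n_cases = nc, beta = NA_real_,
                            se = NA_real_, p = NA_real_, converged = FALSE))
    }
    fit <- suppressWarnings(glm(f, data = df, family = binomial()))
    sep <- any(fitted(fit) > 1 - 1e-10) || any(fitted(fit) < 1e-10)
    if (!fit$converged || sep || anyNA(coef(fit))) {
      return(tibble::tibble(concept_id = cid, n_cases = nc, beta = NA_real_,
                            se = NA_real_, p = NA_real_, converged = FALSE))
    }
    rc <- robust_coefs(fit, hc_type)
    row <- rc[rc$term == "phi", ]
    tibble::tibble(concept_id = cid, n_cases = nc, beta = row$estimate,
                   se = row$std_error,
                   p = 2 * pnorm(-abs(row$estimate / row$std_error)),
                   converged = TRUE)
  })
  m <- nrow(retained)
  res <- res |>
    dplyr::mutate(or = exp(.data$beta),
                  or_lo = exp(.data$beta - qnorm(0.975) * .data$se),
                  or_hi = exp(.data$beta + qnorm(0.975) * .data$se),
                  p_adj = bonferroni(.data$p, m)) |>
    dplyr::relocate("or", "or_lo", "or_hi", .after = "se") |>
    dplyr::arrange(.data$p)
  class(res) <- c("hrp_phewas", class(res))
  res
}
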