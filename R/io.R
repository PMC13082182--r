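# Readers, writers and the end-to-end pipeline.

read_table_any <- function(path, col_types = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "parquet") {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("reading parquet requires the arrow package", call. = FALSE)
    }
    tibble::as_tibble(arrow::read_parquet(path))
  } else if (ext == "tsv") {
    readr::read_tsv(path, col_types = col_types, progress = FALSE)
  } else {
    readr::read_csv(path, col_types = col_types, progress = FALSE)
  }
}

write_table_any <- function(df, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "parquet") {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("writing parquet requires the arrow package", call. = FALSE)
    }
    arrow::write_parquet(df, path)
  } else if (ext == "tsv") {
    readr::write_tsv(df, path, progress = FALSE)
  } else {
    readr::write_csv(df, path, progress = FALSE)
  }
  invisible(path)
}

#' Read a raw heart-rate table with schema validation
#'
#' Expects columns `participant_id`, `timestamp` (ISO-8601), `bpm`. Rows
#' whose bpm is non-numeric, non-finite or non-positive, or whose timestamp
#' fails to parse, are rejected and reported with a message (their 1-based
#' row numbers are attached as `attr(, "rejected_rows")`).
#'
#' @param path CSV, TSV or Parquet file.
#' @return Validated tibble (`participant_id`, `timestamp` POSIXct, `bpm`).
#' @export
read_hr_table <- function(path) {
  raw <- read_table_any(path)
  assert_cols(raw, c("participant_id", "timestamp", "bpm"), "heart-rate table")
  bpm <- suppressWarnings(as.numeric(raw$bpm))
  ts <- raw$timestamp
  if (!inherits(ts, "POSIXt")) {
    ts <- suppressWarnings(readr::parse_datetime(as.character(ts)))
  }
  bad <- which(!is.finite(bpm) | bpm <= 0 | is.na(ts))
  if (length(bad)) {
    message(sprintf("read_hr_table: rejected %d bad row(s) (first few: %s)",
                    length(bad), paste(head(bad, 5), collapse = ", ")))
  }
  out <- tibble::tibble(
    participant_id = as.character(raw$participant_id),
    timestamp = ts, bpm = bpm
  )
  out <- if (length(bad)) out[-bad, ] else out
  attr(out, "rejected_rows") <- bad
  out
}

#' Read a condition-ontology edge list
#'
#' @param path Two-column TSV/CSV with `parent_id`, `child_id`.
#' @return Tibble edge list.
#' @export
read_ontology <- function(path) {
  df <- read_table_any(path)
  assert_cols(df, c("parent_id", "child_id"), "ontology edge list")
  df
}

#' Read genotypes from long-format CSV or VCF 4.2
#'
#' VCF input (via the `vcfR` package) is converted to the package's long
#' format using each record's REF/ALT alleles and the GT field; multiallelic
#' records are carried through with their literal alleles so that downstream
#' biallelic coding can apply the exclusion rule.
#'
#' @param path `.vcf` file, or CSV/TSV/Parquet with columns
#'   `participant_id`, `snv_id`, `allele1`, `allele2`.
#' @return Long genotype tibble.
#' @export
read_genotypes <- function(path) {
  if (tolower(tools::file_ext(path)) == "vcf") {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      stop("reading VCF requires the vcfR package", call. = FALSE)
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    fix <- vcfR::getFIX(v)
    alleles <- lapply(seq_len(nrow(fix)), function(i) {
      c(fix[i, "REF"], strsplit(fix[i, "ALT"], ",")[[1]])
    })
    purrr::map_dfr(seq_len(nrow(gt)), function(i) {
      codes <- strsplit(gsub("\\|", "/", gt[i, ]), "/")
      a <- alleles[[i]]
      tibble::tibble(
        participant_id = colnames(gt),
        snv_id = fix[i, "ID"],
        allele1 = a[as.integer(vapply(codes, `[`, "", 1)) + 1L],
        allele2 = a[as.integer(vapply(codes, `[`, "", 2)) + 1L]
      )
    })
  } else {
    df <- read_table_any(path)
    assert_cols(df, c("participant_id", "snv_id", "allele1", "allele2"),
                "genotype table")
    df
  }
}

#' Write genotypes as a minimal VCF 4.2 (GT only)
#'
#' @param genotypes Long genotype tibble.
#' @param snv_table Output of [compute_allele_frequencies()] supplying
#'   ref/alt per SNV.
#' @param path Output `.vcf` path.
#' @return The path, invisibly.
#' @export
write_vcf <- function(genotypes, snv_table, path) {
  samples <- sort(unique(genotypes$participant_id))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(snv_table)), function(i) {
    sid <- snv_table$snv_id[i]
    ref <- snv_table$ref[i]; alt <- snv_table$alt[i]
    g <- genotypes[genotypes$snv_id == sid, ]
    g <- g[match(samples, g$participant_id), ]
    code <- function(a) ifelse(a == ref, "0", ifelse(a == alt, "1", "."))
    gt <- paste(code(g$allele1), code(g$allele2), sep = "/")
    gt[is.na(g$allele1)] <- "./."
    paste(c("1", as.character(i), sid, ref, alt, ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write all tables of a synthetic cohort to a directory
#'
#' @param sim An `hrp_sim` object from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param format `"csv"` or `"parquet"` (ontology always TSV, config YAML).
#' @return Named vector of written paths, invisibly.
#' @export
write_cohort_tables <- function(sim, dir, format = c("csv", "parquet")) {
  format <- match.arg(format)
  stopifnot(inherits(sim, "hrp_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (nm in c("hr", "covariates", "genotypes", "conditions", "labs",
               "sleep", "truth")) {
    if (is.null(sim[[nm]])) next
    p <- file.path(dir, paste0(nm, ".", format))
    write_table_any(sim[[nm]], p)
    paths[nm] <- p
  }
  p <- file.path(dir, "ontology.tsv")
  readr::write_tsv(sim$ontology, p, progress = FALSE)
  paths["ontology"] <- p
  cfg <- sim$config
  cfg$snv_specs <- as.data.frame(cfg$snv_specs)
  cfg$disease_specs <- as.data.frame(cfg$disease_specs)
  p <- file.path(dir, "config.yaml")
  yaml::write_yaml(unclass(cfg), p)
  paths["config"] <- p
  invisible(paths)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes the stages in study order — weekly aggregation and sine fitting,
#' threshold selection and inclusion filters, genotype-phase association,
#' the phenome-wide scan, disease-focused models (logistic risk, HbA1c,
#' sex-stratified Cox) and two-stage-residual-inclusion Mendelian
#' randomization — and records a manifest of participant counts at every
#' filter step plus all thresholds and seeds for provenance.
#'
#' @param sim An `hrp_sim` object (with the heart-rate stream included) from
#'   [simulate_cohort()], or a list with the same table elements.
#' @param t2dm_concept Concept id for the disease-focused stage (default
#'   201826).
#' @param mr_snv SNV id used as the Mendelian-randomization instrument
#'   (default: first configured SNV).
#' @param grid_step Threshold-scan grid step (default 0.1).
#' @param min_days,min_cases,hba1c_range,hba1c_threshold Filter constants
#'   (defaults: 30 days, 100 cases, 1-30%, 5.6%).
#' @param n_resamples Bootstrap resamples for the MR stage (default 1000 for
#'   a desk-scale run; the headline method uses 100,000).
#' @param seed Run seed; every stochastic stage derives its sub-seed from
#'   it.
#' @return List of class `hrp_pipeline`: `threshold_scan`, `cohort`,
#'   `snv_table`, `assoc`, `phewas`, `t2dm` (logistic/cox/hba1c results),
#'   `mr`, and `manifest` (named list with a stable content hash).
#' @export
run_pipeline <- function(sim, t2dm_concept = 201826, mr_snv = NULL,
                         grid_step = 0.1, min_days = 30, min_cases = 100,
                         hba1c_range = c(1, 30), hba1c_threshold = 5.6,
                         n_resamples = 1000, seed = 1L) {
  stopifnot(!is.null(sim$hr))
  manifest <- list(
    package_version = as.character(utils::packageVersion("hrphase")),
    seed = as.integer(seed), grid_step = grid_step, min_days = min_days,
    min_cases = min_cases, hba1c_range = hba1c_range,
    hba1c_threshold = hba1c_threshold, n_resamples = n_resamples
  )
  counts <- list(n_hr = length(unique(sim$hr$participant_id)))

  # phase extraction
  fits <- extract_phases(sim$hr)
  scan <- select_r2_threshold(fits, grid_step = grid_step)
  thr <- selected_threshold(scan)
  cohort <- apply_inclusion_filters(fits, sim$covariates, threshold = thr,
                                    min_days = min_days)
  counts$n_fit <- sum(fits$fit_ok)
  counts$n_included <- sum(cohort$included)
  manifest$selected_threshold <- thr
  included <- cohort |> dplyr::filter(.data$included)

  # genetics
  snv_table <- compute_allele_frequencies(sim$genotypes)
  dosages <- code_additive(sim$genotypes, snv_table)
  assoc <- associate_snv_phase(included, dosages)
  counts$n_snv_tested <- sum(!is.na(assoc$p))

  # phewas
  pheno <- build_phenotype_matrix(sim$conditions, sim$ontology,
                                  participants = included$participant_id,
                                  min_cases = min_cases)
  phewas <- run_phewas(included, pheno)
  counts$n_concepts_retained <- sum(pheno$concepts$retained)

  # disease-focused stage
  t2dm_flag <- flag_condition(sim$conditions, sim$ontology, t2dm_concept,
                              participants = included$participant_id)
  t2dm_df <- dplyr::left_join(included, t2dm_flag, by = "participant_id")
  logit_res <- logistic_risk(t2dm_df, "flag", "phi")

  hba1c <- max_hba1c_before_end(
    sim$labs, included[, c("participant_id", "monitoring_end")],
    range = hba1c_range, elevated_threshold = hba1c_threshold)
  hba1c_df <- dplyr::inner_join(included, hba1c, by = "participant_id") |>
    dplyr::filter(!is.na(.data$max_hba1c)) |>
    dplyr::mutate(elevated = as.integer(.data$elevated))
  counts$n_hba1c <- nrow(hba1c_df)
  hba1c_res <- if (nrow(hba1c_df) > 20 && length(unique(hba1c_df$elevated)) == 2) {
    logistic_risk(hba1c_df, "elevated", "phi")
  } else {
    NULL
  }

  surv <- build_survival_records(t2dm_df, sim$conditions, sim$ontology,
                                 t2dm_concept)
  cox_res <- tryCatch(cox_age_at_diagnosis(surv, "phi"),
                      error = function(e) NULL)
  counts$n_t2dm_cases <- sum(t2dm_df$flag)

  # mendelian randomization
  if (is.null(mr_snv)) mr_snv <- dosages$snv_id[1]
  mr_df <- dosages |>
    dplyr::filter(.data$snv_id == mr_snv) |>
    dplyr::select("participant_id", "dosage") |>
    dplyr::inner_join(t2dm_df, by = "participant_id")
  mr_res <- mr_2sri(mr_df, outcome = "flag", instrument = "dosage",
                    n_resamples = n_resamples,
                    seed = stage_seed(seed, "boot"))
  counts$n_mr <- mr_res$n

  manifest$counts <- counts
  manifest$hash <- rlang::hash(list(
    manifest[setdiff(names(manifest), "hash")],
    fits, assoc, phewas, logit_res, glance(mr_res)
  ))
  structure(
    list(threshold_scan = scan, cohort = cohort, snv_table = snv_table,
         assoc = assoc, phewas = phewas,
         t2dm = list(logistic = logit_res, hba1c = hba1c_res, cox = cox_res,
                     survival_records = surv),
         mr = mr_res, manifest = manifest),
    class = "hrp_pipeline"
  )
}

#' @export
print.hrp_pipeline <- function(x, ...) {
  m <- x$manifest
  cat("<hrp_pipeline>\n")
  cat(sprintf("  threshold: R^2 > %.1f; included %d of %d participants\n",
              m$selected_threshold, m$counts$n_included, m$counts$n_hr))
  cat(sprintf("  SNVs tested: %d; PheWAS concepts: %d; T2DM cases: %d\n",
              m$counts$n_snv_tested, m$counts$n_concepts_retained,
              m$counts$n_t2dm_cases))
  cat(sprintf("  manifest hash: %s\n", m$hash))
  invisible(x)
}
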