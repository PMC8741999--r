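#' Run the curation pipeline for one case
#'
#' Orchestrates filter -> structural evidence -> classification ->
#' segregation -> diagnostic call for one patient:
#' \enumerate{
#'   \item panel / consequence / MAF filters ([filter_variants()]);
#'   \item structure-derived PP3 codes merged into the evidence where a
#'     mechanism verdict exists ([pp3_from_structure()]);
#'   \item [combine_evidence()] per variant;
#'   \item variants whose pedigree contradicts the inheritance model are
#'     dropped from the report (a failed segregation is never reported as
#'     positive);
#'   \item the diagnostic flag follows the zygosity rule: dominant cases
#'     need one heterozygous P/LP variant; recessive cases need a
#'     homozygous/hemizygous P/LP variant or two heterozygous P/LP
#'     variants in one gene in trans (distinct parental origins or an
#'     explicit `phase_partner`).
#' }
#' Contradictory configurations (e.g. a recessive case with a single
#' heterozygous candidate) yield `diagnostic = FALSE`, not an error.
#'
#' @param variants a `variant_table` for the patient.
#' @param panel a [gene_panel()].
#' @param inheritance `"autosomal_recessive"`, `"autosomal_dominant"`,
#'   `"x_linked"` or `NA`.
#' @param pedigrees optional named list of [pedigree()] objects keyed by
#'   the variant's `cdna` string.
#' @param verdicts optional named list of `mechanism_verdict`s keyed by
#'   `cdna`, used to derive PP3.
#' @param config a [filter_config()].
#' @return A `case_result`: list with `patient_id`, `reported`
#'   (classified variant rows), `excluded_segregation`, `diagnostic`,
#'   `inheritance`.
#' @export
run_case <- function(variants, panel, inheritance = NA_character_,
                     pedigrees = NULL, verdicts = NULL,
                     config = filter_config()) {
  pid <- if (nrow(variants)) variants$patient_id[1] else NA_character_
  cand <- filter_variants(variants, panel, inheritance, config)

  extra <- NULL
  if (!is.null(verdicts)) {
    extra <- lapply(verdicts, function(v) {
      code <- pp3_from_structure(v)
      if (is.null(code)) NULL else list(code)
    })
    extra <- Filter(Negate(is.null), extra)
    if (length(extra) == 0L) extra <- NULL
  }
  cand <- classify_table(cand, extra_codes = extra)

  seg_fail <- logical(nrow(cand))
  if (!is.null(pedigrees) && !is.na(inheritance) && nrow(cand)) {
    for (i in seq_len(nrow(cand))) {
      ped <- pedigrees[[cand$cdna[i]]]
      if (!is.null(ped))
        seg_fail[i] <- isFALSE(segregation_consistent(ped, inheritance))
    }
  }
  reported <- cand[!seg_fail, , drop = FALSE]
  hl_log("run_case.segregation", nrow(cand), nrow(reported),
         "failed family segregation")

  plp <- reported[reported$tier %in% c("Pathogenic", "LikelyPathogenic"), ,
                  drop = FALSE]
  diagnostic <- FALSE
  if (nrow(plp)) {
    if (is.na(inheritance) || inheritance == "autosomal_dominant") {
      diagnostic <- TRUE
    } else {
      # recessive / X-linked: biallelic requirement
      if (any(plp$zygosity %in% c("hom", "hemi"))) diagnostic <- TRUE
      else {
        het <- plp[plp$zygosity == "het", , drop = FALSE]
        for (g in unique(het$gene)) {
          gg <- het[het$gene == g, , drop = FALSE]
          if (nrow(gg) >= 2L && in_trans(gg)) { diagnostic <- TRUE; break }
        }
      }
    }
  }
  structure(list(patient_id = pid, reported = reported,
                 excluded_segregation = cand[seg_fail, , drop = FALSE],
                 diagnostic = diagnostic, inheritance = inheritance),
            class = "case_result")
}

# two het variants in one gene count as in trans when phase partners are
# recorded explicitly, or when their parental origins are distinct
in_trans <- function(gg) {
  if ("phase_partner" %in% names(gg) && any(!is.na(gg$phase_partner))) {
    for (i in seq_len(nrow(gg)))
      if (!is.na(gg$phase_partner[i]) && gg$phase_partner[i] %in% gg$cdna) return(TRUE)
    return(FALSE)
  }
  if ("segregation" %in% names(gg)) {
    orig <- tolower(gg$segregation)
    mat <- grepl("maternal", orig); pat <- grepl("paternal", orig)
    return(any(mat) && any(pat))
  }
  FALSE
}

#' @export
print.case_result <- function(x, ...) {
  cat(sprintf("case %s [%s]: %d reported variant(s), diagnostic = %s\n",
              x$patient_id, x$inheritance, nrow(x$reported), x$diagnostic))
  invisible(x)
}

#' Cohort-level curation summary
#'
#' Headline tallies of a curated cohort: patients with findings (any
#' reportable variant, whatever its tier) over the cohort size, variant
#' counts, novelty (keyed on the reference column: rows attributed to the
#' present work), prior database assertions and the reclassification rate
#' ([reclassification_report()]). Percentages are stored at full
#' precision; rendering rounds rates to one decimal and the
#' reclassification percent to an integer.
#'
#' @param table a `variant_table` of all reported variants (e.g. the
#'   table2 fixture).
#' @param n_cohort total number of patients studied (found plus
#'   undiagnosed).
#' @param mechanisms optional character vector of mechanism labels to
#'   tabulate via [mechanism_breakdown()].
#' @return A `cohort_summary` list.
#' @export
summarize_cohort <- function(table, n_cohort, mechanisms = NULL) {
  if (n_cohort <= 0) stop("cohort size must be positive")
  patients <- unique(table$patient_id)
  n_find <- length(patients)
  novel <- if ("reference" %in% names(table))
    !is.na(table$reference) & grepl("this (work|study)", tolower(table$reference))
  else rep(FALSE, nrow(table))
  rec <- reclassification_report(table)
  out <- list(
    n_patients = n_cohort,
    n_with_findings = n_find,
    findings_rate_percent = 100 * n_find / n_cohort,
    n_variants = nrow(table),
    n_novel = sum(novel),
    n_prior_clinvar = rec$n_prior_asserted,
    n_reclassified = rec$n_changed,
    reclassified_percent = rec$percent_changed,
    mechanism_breakdown = if (is.null(mechanisms)) NULL
                          else mechanism_breakdown(mechanisms)
  )
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("cohort: %d patients, findings in %d (%.1f%%)\n",
              x$n_patients, x$n_with_findings, x$findings_rate_percent))
  cat(sprintf("variants: %d (%d novel, %d with prior ClinVar assertion)\n",
              x$n_variants, x$n_novel, x$n_prior_clinvar))
  if (x$n_prior_clinvar > 0)
    cat(sprintf("reclassified: %d/%d (%d%%)\n", x$n_reclassified,
                x$n_prior_clinvar, round(x$reclassified_percent)))
  if (!is.null(x$mechanism_breakdown)) {
    cat("mechanism breakdown (missense):\n")
    b <- x$mechanism_breakdown
    for (i in seq_len(nrow(b)))
      cat(sprintf("  %-22s %2d (%d%%)\n", b$label[i], b$count[i],
                  round(b$percent[i])))
  }
  invisible(x)
}

#' Serialize a cohort summary to JSON
#' @param summary a `cohort_summary`.
#' @param path output path.
#' @export
write_cohort_report <- function(summary, path) {
  out <- unclass(summary)
  out$schema_version <- "1.0"
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
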