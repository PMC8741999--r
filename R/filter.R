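#' Filter configuration
#'
#' Thresholds for candidate-variant reduction: minor-allele-frequency
#' ceilings of 0.01 for recessive and 0.005 for dominant alleles (both
#' inclusive), and the consequence classes retained (missense, nonsense,
#' frameshift, in-frame indel, splice site).
#'
#' @param maf_recessive MAF ceiling under a recessive model.
#' @param maf_dominant MAF ceiling under a dominant model.
#' @param kept_consequences consequence classes kept.
#' @export
filter_config <- function(maf_recessive = 0.01, maf_dominant = 0.005,
                          kept_consequences = c("missense", "nonsense",
                                                "frameshift", "inframe_indel",
                                                "splice_site")) {
  stopifnot(maf_dominant >= 0, maf_dominant <= maf_recessive, maf_recessive <= 1,
            all(kept_consequences %in% CONSEQUENCES))
  structure(list(maf_recessive = maf_recessive, maf_dominant = maf_dominant,
                 kept_consequences = kept_consequences),
            class = "filter_config")
}

keep_rows <- function(table, keep, stage, reason) {
  hl_log(stage, nrow(table), sum(keep), reason)
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict a variant table to an in-silico gene panel
#'
#' @param table a `variant_table`.
#' @param panel a [gene_panel()].
#' @return the rows whose `gene` is in the panel.
#' @export
filter_by_panel <- function(table, panel) {
  stopifnot(inherits(panel, "gene_panel"))
  if (panel$size == 0L) stop("empty gene panel: refusing to drop every variant")
  keep_rows(table, toupper(table$gene) %in% panel$genes,
            "filter_by_panel", "gene not in panel")
}

#' Keep disease-relevant consequence classes
#'
#' @param table a `variant_table`.
#' @param config a [filter_config()].
#' @export
filter_by_consequence <- function(table, config = filter_config()) {
  keep_rows(table, table$consequence %in% config$kept_consequences,
            "filter_by_consequence", "consequence class excluded")
}

#' Apply the inheritance-aware MAF ceiling
#'
#' Recessive cases keep variants with `af_global <= maf_recessive`,
#' dominant cases `af_global <= maf_dominant` (both inclusive, as the
#' thresholds are stated). A missing frequency cannot justify exclusion:
#' such rows are kept and flagged in the log. When the inheritance model
#' is unknown the looser recessive ceiling is used (logged).
#'
#' @param table a `variant_table` with an `af_global` column (absent
#'   column treated as all-missing).
#' @param model `"autosomal_recessive"`, `"autosomal_dominant"`,
#'   `"x_linked"` or `NA` (unknown).
#' @param config a [filter_config()].
#' @export
filter_by_maf <- function(table, model = NA_character_, config = filter_config()) {
  thr <- if (!is.na(model) && model == "autosomal_dominant")
    config$maf_dominant else config$maf_recessive
  if (is.na(model))
    hl_log("filter_by_maf", nrow(table), nrow(table),
           "inheritance unknown: recessive ceiling applied")
  af <- if ("af_global" %in% names(table)) table$af_global else rep(NA_real_, nrow(table))
  absent <- is.na(af)
  if (any(absent))
    hl_log("filter_by_maf.absent", sum(absent), sum(absent), "AF absent, kept")
  keep_rows(table, absent | af <= thr, "filter_by_maf",
            sprintf("af_global > %g", thr))
}

#' Run panel, consequence and MAF filters
#'
#' The three filters are set intersections, so composition is
#' order-invariant and idempotent.
#'
#' @inheritParams filter_by_maf
#' @inheritParams filter_by_panel
#' @export
filter_variants <- function(table, panel, model = NA_character_,
                            config = filter_config()) {
  table <- filter_by_panel(table, panel)
  table <- filter_by_consequence(table, config)
  filter_by_maf(table, model, config)
}
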