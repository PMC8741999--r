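#' Read an annotated variant table (TSV)
#'
#' Ingestion contract for per-patient annotated variants. The file must be
#' tab-separated with a header; required columns are `patient_id`, `gene`,
#' `transcript`, `cdna`, `consequence` and `zygosity`. Optional columns
#' (`protein`, `dbsnp`, `af_global`, `clinvar`, `criteria`, `reference`,
#' `segregation`, `phenotype`, `after_curation`, ...) are kept when present;
#' missing optional fields become `NA`, never zeros. A YAML column map can
#' adapt exports whose headers differ (see `schema`).
#'
#' @param path TSV file path.
#' @param schema optional named character vector or YAML file path mapping
#'   canonical column names to the file's header names,
#'   e.g. `c(gene = "SYMBOL", cdna = "HGVSc")`.
#' @return A `variant_table` (data frame) with one row per
#'   (patient, gene, cDNA change); criteria strings are validated with
#'   [parse_codes()] at read time.
#' @export
read_variant_table <- function(path, schema = NULL) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE, na.strings = c("NA", ""),
                          colClasses = "character", quote = "")
  if (!is.null(schema)) {
    if (is.character(schema) && length(schema) == 1L && file.exists(schema))
      schema <- unlist(yaml::read_yaml(schema))
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (src %in% names(df)) names(df)[names(df) == src] <- canon
    }
  }
  required <- c("patient_id", "gene", "transcript", "cdna", "consequence", "zygosity")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("variant table schema error: missing required column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(df) > 0) {
    key <- paste(df$patient_id, df$gene, df$cdna, sep = "|")
    if (anyDuplicated(key)) {
      rows <- which(key %in% key[duplicated(key)])
      stop("duplicate (patient_id, gene, cdna) rows at: ",
           paste(rows, collapse = ", "))
    }
    bad <- !df$consequence %in% CONSEQUENCES
    if (any(bad))
      stop("unknown consequence value(s): ",
           paste(unique(df$consequence[bad]), collapse = ", "))
    check_hgvs_consequence(df)
    if ("criteria" %in% names(df)) {
      for (s in df$criteria[!is.na(df$criteria)]) parse_codes(s)
    }
  }
  if ("af_global" %in% names(df)) df$af_global <- as.numeric(df$af_global)
  if ("novel" %in% names(df)) df$novel <- as.logical(df$novel)
  hl_log("read_variant_table", nrow(df), nrow(df))
  class(df) <- c("variant_table", "data.frame")
  attr(df, "source_path") <- path
  df
}

#' Valid consequence classes
#' @export
CONSEQUENCES <- c("missense", "nonsense", "frameshift", "splice_site",
                  "inframe_indel", "synonymous", "intronic", "other")

# consequence must be consistent with the HGVS p. suffix where checkable
check_hgvs_consequence <- function(df) {
  if (!"protein" %in% names(df)) return(invisible(TRUE))
  p <- df$protein
  has <- !is.na(p) & p != ""
  ter <- has & grepl("(\\*\\)?$)|Ter", p) & !grepl("fs", p)
  fs  <- has & grepl("fs", p)
  bad <- (ter & df$consequence != "nonsense") | (fs & df$consequence != "frameshift")
  if (any(bad))
    stop("consequence inconsistent with HGVS protein change at row(s): ",
         paste(which(bad), collapse = ", "))
  invisible(TRUE)
}

#' Write a variant table as TSV
#' @param table a `variant_table`.
#' @param path output path.
#' @export
write_variant_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a ddG replicate table
#'
#' Each row holds a variant label and either (a) replica-level folding
#' free-energy changes (kcal/mol, typically 5 replicas) or (b) a published
#' mean and standard deviation pair. Accepted TSV layouts:
#' `label <tab> r1 <tab> r2 ...` (replica form, >= 1 numeric replicas) or a
#' header with columns `label`, `mean`, `sd` (summary form). In summary
#' form replica-level operations degrade gracefully to the stored summary.
#' Sample (n-1) standard deviation is used for replica sets.
#'
#' @param path TSV/CSV path (separator sniffed from the first line).
#' @return A `ddg_table`: named list of [ddg_replicate_set()] objects.
#' @export
read_ddg_table <- function(path) {
  stopifnot(file.exists(path))
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  hdr <- tolower(strsplit(first, sep, fixed = TRUE)[[1]])
  out <- list()
  if (all(c("label", "mean", "sd") %in% trimws(hdr))) {
    df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
    names(df) <- tolower(names(df))
    for (i in seq_len(nrow(df))) {
      m <- suppressWarnings(as.numeric(df$mean[i])); s <- suppressWarnings(as.numeric(df$sd[i]))
      if (is.na(m) || is.na(s))
        stop("non-numeric ddG cell in row '", df$label[i], "'")
      out[[df$label[i]]] <- ddg_replicate_set(df$label[i], mean = m, sd = s,
                                              n = if ("n" %in% names(df)) as.integer(df$n[i]) else NA_integer_)
    }
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    for (ln in lines) {
      parts <- trimws(strsplit(ln, sep, fixed = TRUE)[[1]])
      lab <- parts[1]
      vals <- suppressWarnings(as.numeric(parts[-1]))
      if (length(vals) == 0L || anyNA(vals))
        stop("non-numeric ddG cell in row '", lab, "'")
      out[[lab]] <- ddg_replicate_set(lab, replicas = vals)
    }
  }
  if (length(out) == 0L) stop("empty ddG table: ", path)
  class(out) <- "ddg_table"
  out
}

#' Per-variant ddG replicate set
#'
#' @param variant_label variant identifier (e.g. an HGVS p. string).
#' @param replicas numeric vector of per-replica ddG values (kcal/mol).
#' @param mean,sd summary form, used when replica values are unavailable.
#' @param n replica count for summary form.
#' @return object of class `ddg_replicate_set` with `mean`, `sd`, `n`,
#'   and `replicas` (NULL in summary form).
#' @export
ddg_replicate_set <- function(variant_label, replicas = NULL, mean = NULL,
                              sd = NULL, n = NA_integer_) {
  if (!is.null(replicas)) {
    stopifnot(length(replicas) >= 1L, all(is.finite(replicas)))
    obj <- list(variant_label = variant_label, replicas = replicas,
                mean = base::mean(replicas),
                sd = if (length(replicas) > 1L) stats::sd(replicas) else 0,
                n = length(replicas), summary_only = FALSE)
  } else {
    stopifnot(is.numeric(mean), is.numeric(sd), sd >= 0)
    obj <- list(variant_label = variant_label, replicas = NULL,
                mean = mean, sd = sd, n = n, summary_only = TRUE)
  }
  class(obj) <- "ddg_replicate_set"
  obj
}

#' @export
print.ddg_replicate_set <- function(x, ...) {
  cat(sprintf("ddG %s: %.2f +/- %.2f kcal/mol (n=%s%s)\n", x$variant_label,
              x$mean, x$sd, x$n, if (x$summary_only) ", summary" else ""))
  invisible(x)
}

#' Read a gene panel file
#'
#' One HGNC symbol per line; `#` comment lines and blank lines ignored.
#' Symbols are uppercase-normalized.
#'
#' @param path panel file.
#' @param name panel name.
#' @return A `gene_panel`: list with `genes` (character set), `name`, `size`.
#' @export
read_gene_panel <- function(path, name = basename(path)) {
  lines <- trimws(readLines(path, warn = FALSE))
  genes <- unique(toupper(lines[nzchar(lines) & !startsWith(lines, "#")]))
  gene_panel(genes, name = name)
}

#' @rdname read_gene_panel
#' @param genes character vector of gene symbols.
#' @export
gene_panel <- function(genes, name = "panel") {
  genes <- unique(toupper(trimws(genes)))
  structure(list(genes = genes, name = name, size = length(genes)),
            class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("gene_panel '%s': %d genes\n", x$name, x$size))
  invisible(x)
}

#' Load a shipped fixture table
#'
#' Fixtures transcribe the published curation and LeuRS evaluation tables
#' and ship a synthetic stand-in deafness panel:
#' \describe{
#'   \item{table2}{28 curated variants in 20 patients (criteria strings,
#'     prior ClinVar assertions, post-curation tiers).}
#'   \item{table3}{20 LARS2 variants with ddG summaries (mean +/- SD of 5
#'     FoldX replicas), structural-effect labels and the transcribed
#'     interface/helix/burial annotations.}
#'   \item{lars2_domains}{the seven LeuRS regions in N-to-C order.}
#'   \item{panel}{synthetic stand-in deafness gene panel.}
#' }
#' Fixture checksums are pinned in `extdata/MANIFEST`.
#'
#' @param name one of `"table2"`, `"table3"`, `"lars2_domains"`, `"panel"`.
#' @return `variant_table`, data frame, or `gene_panel` accordingly.
#' @export
load_fixture <- function(name = c("table2", "table3", "lars2_domains", "panel")) {
  name <- match.arg(name)
  f <- function(x) system.file("extdata", x, package = "hlcur", mustWork = TRUE)
  switch(name,
    table2 = read_variant_table(f("table2_variants.tsv")),
    table3 = {
      df <- utils::read.delim(f("table3_lars2.tsv"), stringsAsFactors = FALSE,
                              na.strings = c("NA", ""))
      df$in_interface <- as.logical(df$in_interface)
      df$in_helix <- as.logical(df$in_helix)
      df$buried <- as.logical(df$buried)
      df
    },
    lars2_domains = utils::read.delim(f("lars2_domains.tsv"), stringsAsFactors = FALSE),
    panel = read_gene_panel(f("deafness_panel_standin.txt"), name = "deafness_standin")
  )
}

#' Verify fixture checksums against the pinned manifest
#' @return TRUE invisibly; stops if any fixture was edited without
#'   updating the manifest.
#' @export
verify_fixtures <- function() {
  dir <- system.file("extdata", package = "hlcur", mustWork = TRUE)
  man <- read.table(file.path(dir, "MANIFEST"), header = FALSE,
                    col.names = c("md5", "file"), stringsAsFactors = FALSE)
  got <- unname(tools::md5sum(file.path(dir, man$file)))
  if (!identical(got, man$md5))
    stop("fixture checksum mismatch: ",
         paste(man$file[got != man$md5], collapse = ", "))
  invisible(TRUE)
}
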