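#' Pedigree members
#'
#' A pedigree is a data frame with one row per member: `id`,
#' `relationship` (free text, `"proband"` exactly once), `affected`
#' (logical) and `genotype` for the variant under test, one of
#' `"biallelic"` (hom/compound het), `"het"`, `"ref"`, or `NA` when not
#' genotyped.
#'
#' @param id,relationship,affected,genotype vectors of equal length.
#' @return data frame of class `pedigree`.
#' @export
pedigree <- function(id, relationship, affected, genotype = NA_character_) {
  df <- data.frame(id = as.character(id), relationship = as.character(relationship),
                   affected = as.logical(affected),
                   genotype = as.character(genotype), stringsAsFactors = FALSE)
  if (sum(df$relationship == "proband") != 1L)
    stop("pedigree must contain exactly one proband")
  bad <- !is.na(df$genotype) & !df$genotype %in% c("biallelic", "het", "ref")
  if (any(bad)) stop("unknown genotype value(s): ",
                     paste(unique(df$genotype[bad]), collapse = ", "))
  class(df) <- c("pedigree", "data.frame")
  df
}

#' Read a pedigree from TSV
#' @param path TSV with columns id, relationship, affected, genotype.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  pedigree(df$id, df$relationship, df$affected, df$genotype)
}

#' Is a variant's segregation consistent with an inheritance model?
#'
#' Checks every genotyped member against the model:
#' \itemize{
#'   \item autosomal recessive: affected members must be biallelic,
#'     unaffected members must not be biallelic;
#'   \item autosomal dominant (and X-linked, treated dominantly for
#'     carriers): affected iff carrier (het or biallelic), among
#'     genotyped members.
#' }
#' Adding a member can only preserve or falsify consistency, never
#' restore it.
#'
#' @param ped a [pedigree()].
#' @param model `"autosomal_recessive"`, `"autosomal_dominant"` or
#'   `"x_linked"`.
#' @return `TRUE`, `FALSE`, or `NA` (indeterminate) when no non-proband
#'   member is genotyped.
#' @examples
#' ped <- pedigree(c("p", "m", "f"), c("proband", "mother", "father"),
#'                 c(TRUE, FALSE, FALSE), c("biallelic", "het", "het"))
#' segregation_consistent(ped, "autosomal_recessive")  # TRUE
#' @export
segregation_consistent <- function(ped, model = c("autosomal_recessive",
                                                  "autosomal_dominant",
                                                  "x_linked")) {
  model <- match.arg(model)
  stopifnot(inherits(ped, "pedigree"))
  gen <- ped[!is.na(ped$genotype), , drop = FALSE]
  if (nrow(gen[gen$relationship != "proband", , drop = FALSE]) == 0L)
    return(NA)
  if (model == "autosomal_recessive") {
    ok <- ifelse(gen$affected, gen$genotype == "biallelic",
                 gen$genotype != "biallelic")
  } else {
    carrier <- gen$genotype %in% c("het", "biallelic")
    ok <- gen$affected == carrier
  }
  all(ok)
}

#' Parse an HGVS protein change
#'
#' Handles `p.Thr629Met`, `p.(Glu638Lys)`, `p.(Ser372*)`,
#' `p.(Leu495fs)` / `p.(Leu495Thrfs*31)` forms.
#'
#' @param p HGVS p. string.
#' @return list with `aa_from`, `position`, `aa_to` (1-letter codes;
#'   `aa_to` is `"*"` for stop gains, `"fs"` for frameshifts) and `kind`
#'   (`missense`, `nonsense`, `frameshift`).
#' @export
parse_protein_change <- function(p) {
  s <- sub("^p\\.", "", trimws(p))
  s <- gsub("[()]", "", s)
  m <- regmatches(s, regexec("^([A-Z][a-z]{2})([0-9]+)(.*)$", s))[[1]]
  if (length(m) == 0L) stop("unparseable protein change: '", p, "'")
  from <- aa3to1(m[2])
  pos <- as.integer(m[3])
  rest <- m[4]
  if (grepl("fs", rest)) return(list(aa_from = from, position = pos, aa_to = "fs",
                                     kind = "frameshift"))
  if (rest %in% c("*", "Ter")) return(list(aa_from = from, position = pos, aa_to = "*",
                                           kind = "nonsense"))
  m2 <- regmatches(rest, regexec("^([A-Z][a-z]{2})", rest))[[1]]
  if (length(m2) == 0L) stop("unparseable protein change: '", p, "'")
  list(aa_from = from, position = pos, aa_to = aa3to1(m2[2]), kind = "missense")
}

AA_3TO1 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
             Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
             Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
             Tyr = "Y", Val = "V")

AA_1 <- unname(AA_3TO1)

aa3to1 <- function(x) {
  out <- AA_3TO1[[x]]
  if (is.null(out)) stop("unknown amino-acid code: '", x, "'")
  out
}
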