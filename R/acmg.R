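#' @name acmg
#' @title Strength-modified ACMG/AMP evidence codes and the five-tier combiner
#'
#' @description
#' Clinical variant curation expresses evidence as ACMG/AMP criterion codes
#' (PVS1, PS1-PS4, PM1-PM6, PP1-PP5 on the pathogenic side; BA1, BS1-BS4,
#' BP1-BP7 on the benign side), each carrying a default strength
#' (VeryStrong, Strong, Moderate, Supporting; BA1 is stand-alone).
#' Gene-specific expert panels re-weight codes with a strength modifier
#' suffix, written in several dialects: `PM3_VS`, `PM3_Strong`, `PP1_Sup`,
#' `PP1_Supporting`, `PP1_Mod`, `BS1_Sup` and so on. [parse_code()]
#' normalizes one token; [combine_evidence()] folds a set of parsed codes
#' into one of Pathogenic / LikelyPathogenic / VUS / LikelyBenign / Benign.
NULL

STRENGTH_LEVELS <- c("Supporting", "Moderate", "Strong", "VeryStrong", "Standalone")

PATH_BASES <- c("PVS1", paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5))
BENIGN_BASES <- c("BA1", paste0("BS", 1:4), paste0("BP", 1:7))

TIER_LEVELS <- c("Benign", "LikelyBenign", "VUS", "LikelyPathogenic", "Pathogenic")

default_strength <- function(base) {
  fam <- sub("[0-9]+$", "", base)
  switch(fam,
         PVS = "VeryStrong", PS = "Strong", PM = "Moderate", PP = "Supporting",
         BA = "Standalone", BS = "Strong", BP = "Supporting",
         stop("unknown evidence code family: ", base))
}

#' Parse one evidence-code token
#'
#' Accepts `BASE` or `BASE_MODIFIER` (case-insensitive) where the modifier
#' is one of Sup/Supporting, M/Mod/Moderate, S/Strong, VS/VeryStrong.
#' `_S` always means Strong (so `PVS1_S` is a downgrade to Strong, never
#' Supporting). A bare token carries its family's default strength.
#'
#' @param token e.g. `"PM3_VS"`, `"PP1_Sup"`, `"PVS1"`.
#' @return An `evidence_code`: list with `base`, `direction`
#'   (`"pathogenic"`/`"benign"`), `default_strength`, `applied_strength`.
#' @examples
#' parse_code("PM3_VS")$applied_strength   # "VeryStrong"
#' parse_code("PVS1")$applied_strength     # "VeryStrong" (default)
#' identical(parse_code("PP1_S"), parse_code("PP1_Strong"))
#' @export
parse_code <- function(token) {
  tok <- trimws(token)
  m <- regmatches(tok, regexec("^([A-Za-z]+[0-9]+)(?:_([A-Za-z]+))?$", tok))[[1]]
  if (length(m) == 0L) stop("unparseable evidence code token: '", token, "'")
  base <- toupper(m[2])
  if (!base %in% c(PATH_BASES, BENIGN_BASES))
    stop("unknown evidence code base in token: '", token, "'")
  mod <- toupper(m[3])
  applied <- if (is.na(mod) || mod == "") {
    default_strength(base)
  } else {
    switch(mod,
           SUP = , SUPPORTING = "Supporting",
           M = , MOD = , MODERATE = "Moderate",
           S = , STRONG = "Strong",
           VS = , VERYSTRONG = "VeryStrong",
           stop("unknown strength modifier in token: '", token, "'"))
  }
  structure(list(base = base,
                 direction = if (base %in% BENIGN_BASES) "benign" else "pathogenic",
                 default_strength = default_strength(base),
                 applied_strength = applied),
            class = "evidence_code")
}

#' @export
print.evidence_code <- function(x, ...) {
  cat(sprintf("%s [%s, %s%s]\n", x$base, x$direction, x$applied_strength,
              if (x$applied_strength != x$default_strength)
                paste0(", default ", x$default_strength) else ""))
  invisible(x)
}

#' Parse a criteria string into a list of evidence codes
#'
#' Splits on commas/semicolons/whitespace, e.g.
#' `"PM2, PM3_S, PP1_Sup, PP4"`.
#' @param s criteria string (or character vector of tokens).
#' @return list of `evidence_code`.
#' @export
parse_codes <- function(s) {
  if (length(s) == 1L) s <- strsplit(s, "[,;[:space:]]+")[[1]]
  s <- s[nzchar(s)]
  lapply(s, parse_code)
}

# Bucket counts at effective (applied) strengths.
# Pathogenic side: vs, s, m, p. Benign side: ba (stand-alone),
# bs (Strong or stronger), bp (Moderate/Supporting).
evidence_counts <- function(codes) {
  vs <- s <- m <- p <- ba <- bs <- bp <- 0L
  for (cd in codes) {
    if (cd$direction == "pathogenic") {
      switch(cd$applied_strength,
             VeryStrong = vs <- vs + 1L,
             Strong = s <- s + 1L,
             Moderate = m <- m + 1L,
             Supporting = p <- p + 1L)
    } else {
      switch(cd$applied_strength,
             Standalone = ba <- ba + 1L,
             VeryStrong = , Strong = bs <- bs + 1L,
             Moderate = , Supporting = bp <- bp + 1L)
    }
  }
  list(vs = vs, s = s, m = m, p = p, ba = ba, bs = bs, bp = bp)
}

#' Combine evidence codes into a five-tier classification
#'
#' Categorical rule combination in the Richards (2015) style with the
#' hearing-loss expert-panel usage this package reproduces:
#' \itemize{
#'   \item Pathogenic: `vs>=2`; or `vs>=1` with (`s>=1` or `m>=2` or
#'     `m>=1 & p>=1` or `p>=2`); or `s>=2`; or `s==1` with (`m>=3` or
#'     `m==2 & p>=2` or `m==1 & p>=4`).
#'   \item LikelyPathogenic: `vs>=1 & m>=1`; `vs>=1 & p>=1`;
#'     `s==1 & 1<=m<=2`; `s==1 & p>=2`; `m>=3`; `m==2 & p>=2`;
#'     `m>=1 & p>=3`.
#'   \item Benign: `ba>=1` (stand-alone, overrides everything) or `bs>=2`.
#'   \item LikelyBenign: `bs==1 & bp>=1` or `bp>=2`.
#'   \item Otherwise VUS; if both a P/LP and a B/LB combination are met
#'     (after the BA1 override) the result is VUS.
#' }
#' A code upgraded to VeryStrong (e.g. `PM3_VS`, `PP1_VS`) counts in the
#' `vs` bucket exactly like PVS1; benign evidence that does not itself
#' reach LikelyBenign/Benign does not force VUS. Counting is over applied
#' strengths, so the combiner is permutation-invariant and monotone in
#' both evidence direction and strength.
#'
#' @param codes list of `evidence_code` (as from [parse_codes()]), or a
#'   single criteria string.
#' @return one of `"Pathogenic"`, `"LikelyPathogenic"`, `"VUS"`,
#'   `"LikelyBenign"`, `"Benign"`.
#' @examples
#' combine_evidence("PM2, PVS1, PP1_Sup")   # Pathogenic
#' combine_evidence("PM2, PP3")             # VUS
#' combine_evidence("BA1, PS2")             # Benign (stand-alone override)
#' combine_evidence("PM2, PM3_Strong, PP4") # LikelyPathogenic
#' @export
combine_evidence <- function(codes) {
  if (is.character(codes)) codes <- parse_codes(codes)
  n <- evidence_counts(codes)
  if (n$ba >= 1L) return("Benign")

  path_P <- (n$vs >= 2L) ||
    (n$vs >= 1L && (n$s >= 1L || n$m >= 2L || (n$m >= 1L && n$p >= 1L) || n$p >= 2L)) ||
    (n$s >= 2L) ||
    (n$s == 1L && (n$m >= 3L || (n$m == 2L && n$p >= 2L) || (n$m == 1L && n$p >= 4L)))
  path_LP <- (n$vs >= 1L && n$m >= 1L) || (n$vs >= 1L && n$p >= 1L) ||
    (n$s == 1L && n$m >= 1L && n$m <= 2L) || (n$s == 1L && n$p >= 2L) ||
    (n$m >= 3L) || (n$m == 2L && n$p >= 2L) || (n$m >= 1L && n$p >= 3L)

  ben_B <- n$bs >= 2L
  ben_LB <- (n$bs == 1L && n$bp >= 1L) || (n$bp >= 2L)

  path_met <- path_P || path_LP
  ben_met <- ben_B || ben_LB
  if (path_met && ben_met) return("VUS")
  if (path_P) return("Pathogenic")
  if (path_LP) return("LikelyPathogenic")
  if (ben_B) return("Benign")
  if (ben_LB) return("LikelyBenign")
  "VUS"
}

#' Classify every row of a variant table
#'
#' Parses each row's `criteria` string and applies [combine_evidence()].
#' Rows without evidence codes are assigned VUS and flagged.
#'
#' @param table a `variant_table` with a `criteria` column.
#' @param extra_codes optional named list: row key
#'   (`"patient|gene|cdna"` or just `cdna`) -> list of additional
#'   `evidence_code`s to merge (e.g. a structure-derived PP3).
#' @return the table with `tier` (character) and `no_evidence` (logical)
#'   columns appended.
#' @export
classify_table <- function(table, extra_codes = NULL) {
  crit <- if ("criteria" %in% names(table)) table$criteria else rep(NA_character_, nrow(table))
  tier <- character(nrow(table))
  noev <- logical(nrow(table))
  for (i in seq_len(nrow(table))) {
    codes <- if (is.na(crit[i]) || !nzchar(trimws(crit[i]))) list() else parse_codes(crit[i])
    if (!is.null(extra_codes)) {
      key1 <- paste(table$patient_id[i], table$gene[i], table$cdna[i], sep = "|")
      add <- extra_codes[[key1]] %||% extra_codes[[table$cdna[i]]]
      if (!is.null(add)) {
        have <- vapply(codes, `[[`, "", "base")
        add <- Filter(function(cd) !cd$base %in% have, add)
        codes <- c(codes, add)
      }
    }
    if (length(codes) == 0L) {
      tier[i] <- "VUS"; noev[i] <- TRUE
    } else {
      tier[i] <- combine_evidence(codes)
    }
  }
  table$tier <- tier
  table$no_evidence <- noev
  table
}

# normalize a prior assertion string to a single tier, a dual assertion,
# or a conflicting interpretation
normalize_prior <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(NA_character_)
  s <- tolower(x)
  if (grepl("conflict", s)) return("Conflicting")
  if (grepl("/", s)) return("Dual")
  if (grepl("likely\\s*path", s)) return("LikelyPathogenic")
  if (grepl("path", s)) return("Pathogenic")
  if (grepl("likely\\s*benign", s)) return("LikelyBenign")
  if (grepl("benign", s)) return("Benign")
  if (grepl("vus|uncertain", s)) return("VUS")
  NA_character_
}

normalize_tier <- function(x) {
  s <- tolower(trimws(x))
  if (grepl("likely\\s*path", s)) return("LikelyPathogenic")
  if (grepl("path", s)) return("Pathogenic")
  if (grepl("likely\\s*benign", s)) return("LikelyBenign")
  if (grepl("benign", s)) return("Benign")
  "VUS"
}

#' Reclassification summary against prior database assertions
#'
#' Compares the curated tier of each variant against its prior assertion.
#' Dual assertions ("Pathogenic/Likely pathogenic") and conflicting
#' interpretations count as changed whenever curation yields any single
#' tier; a single-tier prior counts as changed only when the curated tier
#' differs from it.
#'
#' @param table a `variant_table`; the curated tier is taken from
#'   `tier_col` (default the transcribed `after_curation` column, falling
#'   back to a computed `tier` column).
#' @param tier_col name of the curated tier column.
#' @return list with `n_prior_asserted`, `n_changed`, `percent_changed`
#'   (full precision; `NA` with `undefined = TRUE` when no priors exist),
#'   and `changed` (logical per prior-asserted row, named by variant).
#' @export
reclassification_report <- function(table, tier_col = NULL) {
  if (is.null(tier_col))
    tier_col <- if ("after_curation" %in% names(table)) "after_curation" else "tier"
  stopifnot(tier_col %in% names(table), "clinvar" %in% names(table))
  prior <- vapply(table$clinvar, normalize_prior, "", USE.NAMES = FALSE)
  has_prior <- !is.na(prior)
  n_prior <- sum(has_prior)
  if (n_prior == 0L)
    return(list(n_prior_asserted = 0L, n_changed = 0L,
                percent_changed = NA_real_, undefined = TRUE,
                changed = logical(0)))
  cur <- vapply(table[[tier_col]][has_prior], normalize_tier, "", USE.NAMES = FALSE)
  pri <- prior[has_prior]
  changed <- pri %in% c("Dual", "Conflicting") | (!pri %in% c("Dual", "Conflicting") & pri != cur)
  names(changed) <- paste(table$gene[has_prior], table$cdna[has_prior])
  list(n_prior_asserted = n_prior,
       n_changed = sum(changed),
       percent_changed = 100 * sum(changed) / n_prior,
       undefined = FALSE,
       changed = changed)
}
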