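#' Audiometric summaries
#'
#' Pure-tone audiometry at 0.5, 1, 2 and 4 kHz underlies the case
#' descriptions: [pta()] is the four-frequency pure-tone average,
#' [severity()] bins it into moderate (41-70 dB HL), severe (71-95 dB HL)
#' and profound (> 95 dB HL), and [audiogram_shape()] labels the
#' audiometric configuration.
#'
#' @param audiogram named numeric vector of hearing thresholds in dB HL
#'   with names `"0.5"`, `"1"`, `"2"`, `"4"` (kHz).
#' @return `pta()`: the arithmetic mean of the four thresholds.
#' @examples
#' pta(c("0.5" = 50, "1" = 55, "2" = 60, "4" = 55))  # 55
#' severity(95)    # "severe"
#' severity(95.1)  # "profound"
#' @export
pta <- function(audiogram) {
  freqs <- c("0.5", "1", "2", "4")
  miss <- setdiff(freqs, names(audiogram))
  if (length(miss))
    stop("audiogram missing frequency(ies): ", paste(miss, collapse = ", "), " kHz")
  v <- audiogram[freqs]
  stopifnot(all(v >= -10 & v <= 130))
  mean(v)
}

#' @rdname pta
#' @param pta_db pure-tone average in dB HL.
#' @return `severity()`: `"moderate"`, `"severe"`, `"profound"`, or
#'   `"below_range"` (< 41 dB HL). A total, monotone step function;
#'   between printed integer bounds the lower bin extends to its upper
#'   neighbor's start (70 < x <= 95 is severe).
#' @export
severity <- function(pta_db) {
  vapply(pta_db, function(x) {
    if (x > 95) "profound"
    else if (x > 70) "severe"
    else if (x >= 41) "moderate"
    else "below_range"
  }, "")
}

#' @rdname pta
#' @param slope_db slope/flatness criterion in dB (default 15, common
#'   audiometric convention; the shape classes themselves are standard
#'   but carry no published numeric rule).
#' @return `audiogram_shape()`: one of `"high_frequency"`,
#'   `"low_frequency"`, `"u_shaped"`, `"flat"`. Rules, in precedence
#'   order: high-frequency when mean(2,4) - mean(0.5,1) >= slope;
#'   low-frequency for the reverse; U-shaped when the mid frequencies
#'   (1,2) exceed the edges (0.5,4) by >= slope; otherwise flat (which
#'   also covers max - min <= slope). Exactly one label per audiogram.
#' @export
audiogram_shape <- function(audiogram, slope_db = 15) {
  freqs <- c("0.5", "1", "2", "4")
  stopifnot(all(freqs %in% names(audiogram)))
  v <- audiogram[freqs]
  high <- mean(v[c("2", "4")]) - mean(v[c("0.5", "1")])
  mid <- mean(v[c("1", "2")]) - mean(v[c("0.5", "4")])
  if (high >= slope_db) return("high_frequency")
  if (-high >= slope_db) return("low_frequency")
  if (mid >= slope_db) return("u_shaped")
  "flat"
}

#' Read audiograms from TSV
#'
#' Expects columns `patient_id`, `ear`, `hz500`, `hz1000`, `hz2000`,
#' `hz4000`.
#' @param path TSV path.
#' @return data frame with appended `pta`, `severity`, `shape` columns.
#' @export
read_audiograms <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "ear", "hz500", "hz1000", "hz2000", "hz4000")
  stopifnot(all(need %in% names(df)))
  ag <- function(i) c("0.5" = df$hz500[i], "1" = df$hz1000[i],
                      "2" = df$hz2000[i], "4" = df$hz4000[i])
  df$pta <- vapply(seq_len(nrow(df)), function(i) pta(ag(i)), 0)
  df$severity <- severity(df$pta)
  df$shape <- vapply(seq_len(nrow(df)), function(i) audiogram_shape(ag(i)), "")
  df
}
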