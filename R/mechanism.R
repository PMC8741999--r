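#' Is a ddG replicate set significantly destabilizing?
#'
#' A variant is called destabilizing when its mean folding free-energy
#' change exceeds the threshold, 1.6 kcal/mol by default (twice the
#' replica standard deviation of the force-field protocol). "Above" is
#' strict: a mean of exactly 1.6 is not destabilizing.
#'
#' @param ddg a [ddg_replicate_set()].
#' @param threshold kcal/mol.
#' @return logical.
#' @export
ddg_classify <- function(ddg, threshold = 1.6) {
  stopifnot(inherits(ddg, "ddg_replicate_set"))
  ddg$mean > threshold
}

SIDECHAIN_CHARGE <- c(D = -1L, E = -1L, K = 1L, R = 1L, H = 0L)

#' Formal side-chain charge change of a substitution
#'
#' Asp/Glu carry -1, Lys/Arg +1, His and all others 0 at the formal-charge
#' level used for surface-electrostatics triage.
#'
#' @param aa_from,aa_to 1-letter amino-acid codes.
#' @return integer: `charge(aa_to) - charge(aa_from)`.
#' @examples
#' charge_delta("E", "K")  # +2
#' charge_delta("R", "H")  # -1
#' @export
charge_delta <- function(aa_from, aa_to) {
  ch <- function(a) {
    a <- toupper(a)
    if (!a %in% AA_1) stop("nonstandard amino-acid code: '", a, "'")
    if (a %in% names(SIDECHAIN_CHARGE)) SIDECHAIN_CHARGE[[a]] else 0L
  }
  ch(aa_to) - ch(aa_from)
}

#' Assign a structural mechanism to a variant
#'
#' Triage of a variant's structural effect, in precedence order:
#' \enumerate{
#'   \item `LoF` for nonsense/frameshift consequences;
#'   \item `interface_interaction` when the residue belongs to the
#'     ligand-interface set;
#'   \item `electrostatic_surface` when the substitution changes the
#'     formal side-chain charge (`|delta| >= 1`) *and* the residue is
#'     surface-exposed (fails the burial gate);
#'   \item `stability` when the mean ddG is significantly destabilizing
#'     ([ddg_classify()]), or the substitution introduces or removes a
#'     proline inside an annotated helix;
#'   \item `nonconclusive` otherwise.
#' }
#'
#' Burial can be supplied directly (`buried =`), or derived from a model
#' via [burial_proxy()] when `model` is given (`buried` then defaults to
#' `burial_proxy(...) >= burial_cutoff`).
#'
#' @param consequence consequence class of the variant.
#' @param protein_change HGVS p. string (required for missense).
#' @param ddg optional [ddg_replicate_set()].
#' @param in_interface logical: residue in the ligand-interface set.
#' @param in_helix logical: residue inside an annotated alpha-helix
#'   (per-residue secondary-structure annotation is an input, not
#'   computed).
#' @param buried logical: residue fails the surface-exposure gate.
#' @param model optional `structure_model` used to compute burial.
#' @param chain chain for `model` lookup.
#' @param config list of thresholds: `ddg_threshold` (1.6 kcal/mol),
#'   `burial_cutoff` (neighbor count at which a residue counts as
#'   buried; default 45, calibrated on the synthetic globule generator),
#'   `shell_radius` (8 Angstrom).
#' @return A `mechanism_verdict`: list with `label` (one of `LoF`,
#'   `stability`, `electrostatic_surface`, `interface_interaction`,
#'   `nonconclusive`) and `measurements`.
#' @export
assign_mechanism <- function(consequence, protein_change = NULL, ddg = NULL,
                             in_interface = FALSE, in_helix = FALSE,
                             buried = FALSE, model = NULL, chain = "A",
                             config = mechanism_config()) {
  meas <- list()
  if (consequence %in% c("nonsense", "frameshift"))
    return(mechanism_verdict("LoF", meas))
  if (is.null(protein_change))
    stop("protein_change required for missense mechanism assignment")
  pc <- parse_protein_change(protein_change)
  if (pc$kind != "missense")
    return(mechanism_verdict("LoF", list(protein_change = protein_change)))
  meas$position <- pc$position
  meas$charge_delta <- charge_delta(pc$aa_from, pc$aa_to)
  if (!is.null(ddg)) {
    meas$ddg_mean <- ddg$mean
    meas$ddg_sd <- ddg$sd
  }
  if (!is.null(model)) {
    meas$burial_count <- burial_proxy(model, list(chain = chain, resseq = pc$position),
                                      config$shell_radius)
    buried <- meas$burial_count >= config$burial_cutoff
  }
  meas$buried <- isTRUE(buried)
  meas$in_interface <- isTRUE(in_interface)

  if (isTRUE(in_interface))
    return(mechanism_verdict("interface_interaction", meas))
  if (abs(meas$charge_delta) >= 1L && !isTRUE(buried))
    return(mechanism_verdict("electrostatic_surface", meas))
  destab <- !is.null(ddg) && ddg_classify(ddg, config$ddg_threshold)
  proline <- (pc$aa_from == "P" || pc$aa_to == "P") && isTRUE(in_helix)
  meas$proline_in_helix <- proline
  if (destab || proline)
    return(mechanism_verdict("stability", meas))
  mechanism_verdict("nonconclusive", meas)
}

#' @rdname assign_mechanism
#' @export
mechanism_config <- function(ddg_threshold = 1.6, burial_cutoff = 45,
                             shell_radius = 8.0) {
  list(ddg_threshold = ddg_threshold, burial_cutoff = burial_cutoff,
       shell_radius = shell_radius)
}

mechanism_verdict <- function(label, measurements) {
  stopifnot(label %in% c("LoF", "stability", "electrostatic_surface",
                         "interface_interaction", "nonconclusive"))
  structure(list(label = label, measurements = measurements),
            class = "mechanism_verdict")
}

#' @export
print.mechanism_verdict <- function(x, ...) {
  cat("mechanism:", x$label, "\n")
  if (length(x$measurements)) utils::str(x$measurements, give.attr = FALSE)
  invisible(x)
}

#' Derive a structure-based PP3 from a mechanism verdict
#'
#' A conclusive structural mechanism (stability, electrostatic surface,
#' or interface interaction) supplies computational supporting evidence
#' for pathogenicity: PP3 at Supporting strength. A nonconclusive verdict
#' yields no code, and LoF verdicts yield no code either (loss of
#' function is PVS1 territory, supplied upstream, not duplicated here).
#' BP4 is never emitted automatically.
#'
#' @param verdict a `mechanism_verdict`.
#' @return an `evidence_code` (PP3) or `NULL`.
#' @export
pp3_from_structure <- function(verdict) {
  stopifnot(inherits(verdict, "mechanism_verdict"))
  if (verdict$label %in% c("stability", "electrostatic_surface",
                           "interface_interaction"))
    parse_code("PP3")
  else NULL
}

#' Mechanism assignment over the LARS2 evaluation fixture
#'
#' Runs [assign_mechanism()] on every row of a table in the layout of
#' [load_fixture("table3")][load_fixture()]: ddG summaries, protein
#' changes, and transcribed interface/helix/burial annotations.
#'
#' @param tab3 the table3 fixture (or a table with the same columns).
#' @return the table with a `mechanism` column appended.
#' @export
assign_mechanism_table <- function(tab3) {
  lab <- character(nrow(tab3))
  for (i in seq_len(nrow(tab3))) {
    ddg <- if (is.na(tab3$ddg_mean[i])) NULL else
      ddg_replicate_set(tab3$protein[i], mean = tab3$ddg_mean[i],
                        sd = tab3$ddg_sd[i], n = 5L)
    v <- assign_mechanism(tab3$consequence[i], tab3$protein[i], ddg = ddg,
                          in_interface = tab3$in_interface[i],
                          in_helix = tab3$in_helix[i],
                          buried = tab3$buried[i])
    lab[i] <- v$label
  }
  tab3$mechanism <- lab
  tab3
}

#' Mechanism breakdown over missense variants
#'
#' Counts and percentages of each mechanism label over the missense
#' subset (LoF rows excluded from the denominator). Percentages are
#' stored at full precision; `round_percent = TRUE` rounds to integers
#' for rendering.
#'
#' @param labels character vector of mechanism labels.
#' @param round_percent round percentages to integers.
#' @return data frame `label`, `count`, `percent`.
#' @export
mechanism_breakdown <- function(labels, round_percent = FALSE) {
  mis <- labels[labels != "LoF"]
  lv <- c("stability", "electrostatic_surface", "interface_interaction",
          "nonconclusive")
  cnt <- vapply(lv, function(l) sum(mis == l), 0L)
  pct <- 100 * cnt / length(mis)
  if (round_percent) pct <- round(pct)
  data.frame(label = lv, count = unname(cnt), percent = unname(pct))
}
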