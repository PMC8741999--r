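#' Optimal rigid superposition of two conformations (Kabsch)
#'
#' Pairs atoms by `(chain, residue, atom name)` over residues present in
#' both models, restricted to the backbone set, and computes the
#' least-squares optimal rotation (SVD with reflection excluded) and
#' translation of the mobile model onto the reference. Reports the global
#' RMSD over paired atoms after the transform, and per-residue RMSD over
#' each residue's paired backbone atoms.
#'
#' @param mobile,reference `structure_model`s of the two conformations.
#' @param atom_set atom names paired (default backbone N, CA, C, O).
#' @return list of class `superposition` with `rotation` (3x3,
#'   det = +1), `translation` (length-3, applied as `x %*% t(R) + t`),
#'   `global_rmsd`, `per_residue_rmsd` (named by residue number) and
#'   `n_atoms`.
#' @export
kabsch_superpose <- function(mobile, reference, atom_set = c("N", "CA", "C", "O")) {
  key <- function(m) paste(m$chain, m$resseq, m$icode, m$atom_name, sep = "|")
  mob <- mobile[mobile$atom_name %in% atom_set & !mobile$het, , drop = FALSE]
  ref <- reference[reference$atom_name %in% atom_set & !reference$het, , drop = FALSE]
  common <- intersect(key(mob), key(ref))
  if (length(common) < 3L)
    stop("need at least 3 paired atoms for superposition (got ", length(common), ")")
  mob <- mob[match(common, key(mob)), , drop = FALSE]
  ref <- ref[match(common, key(ref)), , drop = FALSE]
  P <- as.matrix(mob[, c("x", "y", "z")])
  Q <- as.matrix(ref[, c("x", "y", "z")])
  fit <- kabsch_fit(P, Q)
  Pt <- sweep(P %*% t(fit$rotation), 2, fit$translation, `+`)
  d2 <- rowSums((Pt - Q)^2)
  resid_key <- paste(ref$chain, ref$resseq, ref$icode, sep = "|")
  per_res <- vapply(split(d2, resid_key), function(v) sqrt(mean(v)), 0)
  # order per-residue profile by chain then residue number
  ord <- order(ref$chain[!duplicated(resid_key)][match(names(per_res), unique(resid_key))])
  parts <- strsplit(names(per_res), "|", fixed = TRUE)
  ord <- order(vapply(parts, `[[`, "", 1), as.integer(vapply(parts, `[[`, "", 2)))
  per_res <- per_res[ord]
  names(per_res) <- vapply(strsplit(names(per_res), "|", fixed = TRUE),
                           function(p) paste0(p[2], p[3]), "")
  structure(list(rotation = fit$rotation, translation = fit$translation,
                 global_rmsd = sqrt(mean(d2)), per_residue_rmsd = per_res,
                 n_atoms = length(common)),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition over %d atoms: global RMSD %.3f A (%d residues)\n",
              x$n_atoms, x$global_rmsd, length(x$per_residue_rmsd)))
  invisible(x)
}

# Kabsch on raw coordinate matrices (n x 3): proper rotation only.
kabsch_fit <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), nrow(P) >= 3L)
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  if (qr(P0)$rank < 2L || qr(Q0)$rank < 2L)
    stop("degenerate (collinear) point set: rotation not uniquely defined")
  H <- t(P0) %*% Q0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- as.numeric(cq - R %*% cp)
  Pt <- sweep(P %*% t(R), 2, t_vec, `+`)
  list(rotation = R, translation = t_vec,
       rmsd = sqrt(mean(rowSums((Pt - Q)^2))))
}

#' Detect motile regions from a per-residue RMSD profile
#'
#' Maximal runs of at least `min_len` consecutive residues whose RMSD
#' exceeds the threshold. `"auto"` sets the threshold to
#' `mean + 2 * SD` of the profile.
#'
#' @param per_residue_rmsd named numeric vector (names = residue numbers),
#'   e.g. from [kabsch_superpose()].
#' @param min_len minimum run length (default 5).
#' @param threshold numeric (Angstrom) or `"auto"`.
#' @return data frame with columns `start`, `end` (residue numbers,
#'   ascending); zero rows when nothing exceeds the threshold.
#' @export
detect_motile_regions <- function(per_residue_rmsd, min_len = 5L, threshold = "auto") {
  stopifnot(length(per_residue_rmsd) > 0L)
  if (identical(threshold, "auto"))
    threshold <- mean(per_residue_rmsd) + 2 * stats::sd(per_residue_rmsd)
  res <- suppressWarnings(as.integer(names(per_residue_rmsd)))
  if (anyNA(res)) res <- seq_along(per_residue_rmsd)
  ord <- order(res)
  res <- res[ord]
  hot <- per_residue_rmsd[ord] > threshold
  out <- data.frame(start = integer(0), end = integer(0))
  i <- 1L
  while (i <= length(res)) {
    if (hot[i]) {
      j <- i
      while (j < length(res) && hot[j + 1L] && res[j + 1L] == res[j] + 1L) j <- j + 1L
      if (j - i + 1L >= min_len)
        out <- rbind(out, data.frame(start = res[i], end = res[j]))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# heavy side-chain atoms of one residue; CA fallback (glycine or
# CB-less toy residues) marked with the "fallback" attribute
sidechain_atoms <- function(model, chain, resseq, icode = "") {
  ra <- residue_atoms(model, chain, resseq, icode)
  if (nrow(ra) == 0L)
    stop(sprintf("selector %s:%s%s resolves to no atoms", chain, resseq, icode))
  sc <- ra[!ra$atom_name %in% c("N", "CA", "C", "O", "OXT") &
           toupper(ra$element) != "H", , drop = FALSE]
  if (nrow(sc) == 0L) {
    sc <- ra[ra$atom_name == "CA", , drop = FALSE]
    if (nrow(sc) == 0L) stop(sprintf("residue %s:%s has no side-chain or CA atom",
                                     chain, resseq))
    attr(sc, "fallback") <- TRUE
  } else attr(sc, "fallback") <- FALSE
  sc
}

#' Minimum side-chain heavy-atom distance between two residues
#'
#' Side chain = heavy atoms excluding backbone N, CA, C, O (and OXT).
#' For glycine (or toy residues without side-chain atoms) the CA position
#' is used and the result carries `attr(, "fallback") = TRUE`.
#'
#' @param model a `structure_model`.
#' @param a,b residue selectors: `list(chain =, resseq =)` or `"A:12"`.
#' @return minimum Euclidean distance in Angstrom.
#' @export
sidechain_min_distance <- function(model, a, b) {
  a <- as_selector(a); b <- as_selector(b)
  sa <- sidechain_atoms(model, a$chain, a$resseq)
  sb <- sidechain_atoms(model, b$chain, b$resseq)
  d <- min(cross_dist(as.matrix(sa[, c("x", "y", "z")]),
                      as.matrix(sb[, c("x", "y", "z")])))
  attr(d, "fallback") <- attr(sa, "fallback") || attr(sb, "fallback")
  d
}

as_selector <- function(x) {
  if (is.list(x)) return(x)
  parts <- strsplit(as.character(x), ":", fixed = TRUE)[[1]]
  if (length(parts) == 2L) list(chain = parts[1], resseq = as.integer(parts[2]))
  else list(chain = "A", resseq = as.integer(parts[1]))
}

cross_dist <- function(A, B) {
  # pairwise Euclidean distances between rows of A and rows of B
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, `+`) - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

#' Residues whose side chains lie within a cutoff of a center residue
#'
#' All residues of the model (excluding the center and its sequence
#' neighbors i-1, i+1 in the same chain) whose minimum side-chain
#' heavy-atom distance to the center is below `cutoff`, ascending by
#' distance.
#'
#' @param model a `structure_model`.
#' @param center residue selector.
#' @param cutoff shell radius in Angstrom (default 5.0, the wild-type
#'   contact convention).
#' @return data frame `chain`, `resseq`, `distance`.
#' @export
neighbor_shell <- function(model, center, cutoff = 5.0) {
  center <- as_selector(center)
  prot <- model[!model$het, , drop = FALSE]
  resdf <- unique(prot[, c("chain", "resseq")])
  keep <- !(resdf$chain == center$chain &
            abs(resdf$resseq - center$resseq) <= 1L)
  resdf <- resdf[keep, , drop = FALSE]
  if (nrow(resdf) == 0L || cutoff <= 0)
    return(data.frame(chain = character(0), resseq = integer(0),
                      distance = numeric(0)))
  d <- vapply(seq_len(nrow(resdf)), function(i)
    as.numeric(sidechain_min_distance(model, center,
                                      list(chain = resdf$chain[i],
                                           resseq = resdf$resseq[i]))), 0)
  sel <- d < cutoff
  out <- data.frame(chain = resdf$chain[sel], resseq = resdf$resseq[sel],
                    distance = d[sel])
  out[order(out$distance), , drop = FALSE]
}

#' Mean side-chain distance from a center residue to named partners
#'
#' Arithmetic mean of [sidechain_min_distance()] over the partners, the
#' convention used for reporting wild-type contact-shell averages.
#'
#' @param model a `structure_model`.
#' @param center residue selector.
#' @param partners list of residue selectors (non-empty).
#' @export
avg_shell_distance <- function(model, center, partners) {
  if (length(partners) == 0L) stop("partners must be non-empty")
  mean(vapply(partners, function(p)
    as.numeric(sidechain_min_distance(model, center, p)), 0))
}

#' Protein residues at a ligand interface
#'
#' Residues of the protein chains having any heavy atom within `cutoff`
#' of any heavy atom of the ligand chain (the convention used to fix
#' tRNA-contacting residues at 5 Angstrom).
#'
#' @param model a `structure_model` containing protein and ligand chains.
#' @param ligand_chain chain id of the ligand (e.g. a tRNA chain).
#' @param cutoff contact distance in Angstrom (default 5.0).
#' @return data frame `chain`, `resseq` of interface residues.
#' @export
interface_residues <- function(model, ligand_chain, cutoff = 5.0) {
  if (!ligand_chain %in% model$chain)
    stop("ligand chain '", ligand_chain, "' absent from model")
  heavy <- toupper(model$element) != "H"
  lig <- model[model$chain == ligand_chain & heavy, , drop = FALSE]
  prot <- model[model$chain != ligand_chain & heavy, , drop = FALSE]
  if (nrow(prot) == 0L)
    return(data.frame(chain = character(0), resseq = integer(0)))
  d <- cross_dist(as.matrix(prot[, c("x", "y", "z")]),
                  as.matrix(lig[, c("x", "y", "z")]))
  near <- apply(d, 1, min) < cutoff
  out <- unique(data.frame(chain = prot$chain[near], resseq = prot$resseq[near]))
  rownames(out) <- NULL
  out[order(out$chain, out$resseq), , drop = FALSE]
}

#' Burial proxy: heavy-atom neighbor count around a residue's side chain
#'
#' Counts heavy atoms belonging to *other* residues within `shell_radius`
#' of the centroid of the center residue's side-chain heavy atoms (CA for
#' glycine-like residues). Higher counts mean more buried; used as the
#' surface-exposure gate for the electrostatic mechanism.
#'
#' @param model a `structure_model`.
#' @param center residue selector.
#' @param shell_radius Angstrom (default 8.0).
#' @return integer neighbor count.
#' @export
burial_proxy <- function(model, center, shell_radius = 8.0) {
  center <- as_selector(center)
  sc <- sidechain_atoms(model, center$chain, center$resseq)
  centroid <- colMeans(as.matrix(sc[, c("x", "y", "z")]))
  others <- model[!(model$chain == center$chain &
                    model$resseq == center$resseq) &
                  toupper(model$element) != "H", , drop = FALSE]
  if (nrow(others) == 0L) return(0L)
  d <- sqrt(colSums((t(as.matrix(others[, c("x", "y", "z")])) - centroid)^2))
  sum(d < shell_radius)
}

#' Screen homology-modeling template candidates
#'
#' Keeps candidates with sequence identity strictly greater than
#' `identity_min` and crystallographic resolution strictly less than
#' `resolution_max`, ranked by identity (descending) with resolution
#' (ascending) as tiebreak.
#'
#' @param candidates data frame with columns `id`, `identity` (fraction
#'   in 0..1) and `resolution` (Angstrom).
#' @param identity_min identity cutoff, default 0.36 (strict `>`).
#' @param resolution_max resolution cutoff, default 2.5 (strict `<`);
#'   a 2.4 value is also used in some screening protocols and can be
#'   set here.
#' @return the accepted rows, ranked.
#' @export
template_screen <- function(candidates, identity_min = 0.36, resolution_max = 2.5) {
  stopifnot(all(c("id", "identity", "resolution") %in% names(candidates)),
            all(candidates$identity >= 0 & candidates$identity <= 1),
            all(candidates$resolution > 0))
  ok <- candidates$identity > identity_min & candidates$resolution < resolution_max
  out <- candidates[ok, , drop = FALSE]
  out <- out[order(-out$identity, out$resolution), , drop = FALSE]
  rownames(out) <- NULL
  out
}
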