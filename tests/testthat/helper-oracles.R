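# Independent oracles, written against the rule definitions rather than
# the package implementation.

# ---- brute-force rigid-superposition oracle -------------------------------
# Dense grid search over ZYZ Euler-angle rotations with successive
# refinement; translation handled by centroid matching. Uses only the
# identity  sum_i |R p_i - q_i|^2 = sum(|p|^2 + |q|^2) - 2 tr(R M),
# M = sum_i q_i p_i^T, to score the grid.
grid_rmsd_oracle <- function(P, Q, levels = 5L, coarse_step = 10) {
  stopifnot(nrow(P) == nrow(Q))
  n <- nrow(P)
  P0 <- sweep(P, 2, colMeans(P))
  Q0 <- sweep(Q, 2, colMeans(Q))
  M <- t(Q0) %*% P0
  c0 <- sum(P0^2 + Q0^2) / n

  score_grid <- function(g) {
    ca <- cos(g$a); sa <- sin(g$a); cb <- cos(g$b); sb <- sin(g$b)
    cg <- cos(g$g); sg <- sin(g$g)
    (ca * cb * cg - sa * sg) * M[1, 1] +
      (-ca * cb * sg - sa * cg) * M[1, 2] +
      (ca * sb) * M[1, 3] +
      (sa * cb * cg + ca * sg) * M[2, 1] +
      (-sa * cb * sg + ca * cg) * M[2, 2] +
      (sa * sb) * M[2, 3] +
      (-sb * cg) * M[3, 1] +
      (sb * sg) * M[3, 2] +
      cb * M[3, 3]
  }

  # coarse scan, then local grid refinement around each of the top
  # candidates (the Euler chart is degenerate near b = 0/pi, so a single
  # refinement path can stall; pooling candidates avoids that)
  step <- coarse_step * pi / 180
  g <- expand.grid(a = seq(0, 2 * pi, by = step),
                   b = seq(0, pi, by = step),
                   g = seq(0, 2 * pi, by = step))
  cross <- score_grid(g)
  top <- g[order(cross, decreasing = TRUE)[1:25], ]
  best_cross <- max(cross)
  for (lv in seq_len(levels - 1L)) {
    newstep <- step / 5
    pooled <- do.call(rbind, lapply(seq_len(nrow(top)), function(i) {
      expand.grid(a = seq(top$a[i] - step, top$a[i] + step, by = newstep),
                  b = seq(top$b[i] - step, top$b[i] + step, by = newstep),
                  g = seq(top$g[i] - step, top$g[i] + step, by = newstep))
    }))
    cross <- score_grid(pooled)
    ord <- order(cross, decreasing = TRUE)
    top <- pooled[ord[1:min(10L, nrow(pooled))], ]
    best_cross <- max(best_cross, cross[ord[1]])
    step <- newstep
  }
  sqrt(max(c0 - 2 * best_cross / n, 0))
}

# ---- truth-table combiner oracle ------------------------------------------
# Rule combinations expressed as minimum-count requirements; a tier is
# reached when any of its combinations is satisfied.
ORACLE_P_COMBOS <- list(
  c(vs = 2), c(vs = 1, s = 1), c(vs = 1, m = 2), c(vs = 1, m = 1, p = 1),
  c(vs = 1, p = 2), c(s = 2), c(s = 1, m = 3), c(s = 1, m = 2, p = 2),
  c(s = 1, m = 1, p = 4))
ORACLE_LP_COMBOS <- list(
  c(vs = 1, m = 1), c(vs = 1, p = 1), c(s = 1, m = 1), c(s = 1, p = 2),
  c(m = 3), c(m = 2, p = 2), c(m = 1, p = 3))

combo_met <- function(combos, counts) {
  any(vapply(combos, function(cmb)
    all(counts[names(cmb)] >= cmb), TRUE))
}

oracle_combine_counts <- function(vs = 0, s = 0, m = 0, p = 0,
                                  ba = 0, bs = 0, bp = 0) {
  counts <- c(vs = vs, s = s, m = m, p = p)
  if (ba >= 1) return("Benign")
  pP <- combo_met(ORACLE_P_COMBOS, counts)
  pLP <- combo_met(ORACLE_LP_COMBOS, counts)
  bB <- bs >= 2
  bLB <- (bs == 1 && bp >= 1) || bp >= 2
  if ((pP || pLP) && (bB || bLB)) return("VUS")
  if (pP) return("Pathogenic")
  if (pLP) return("LikelyPathogenic")
  if (bB) return("Benign")
  if (bLB) return("LikelyBenign")
  "VUS"
}

# map a multiset of default-strength bases to oracle buckets
oracle_combine_bases <- function(bases) {
  n <- table(factor(bases, levels = c("PVS1", "PS1", "PM1", "PP1",
                                      "BA1", "BS1", "BP1")))
  oracle_combine_counts(vs = n[["PVS1"]], s = n[["PS1"]], m = n[["PM1"]],
                        p = n[["PP1"]], ba = n[["BA1"]], bs = n[["BS1"]],
                        bp = n[["BP1"]])
}

# all multisets of size <= k from the given bases
all_multisets <- function(bases, k) {
  out <- list(character(0))
  grow <- function(prefix, remaining, depth) {
    if (depth == 0L) return()
    for (i in seq_along(remaining)) {
      ms <- c(prefix, remaining[i])
      out[[length(out) + 1L]] <<- ms
      grow(ms, remaining[i:length(remaining)], depth - 1L)
    }
  }
  grow(character(0), bases, k)
  out
}

TIERS_ORDERED <- c("Benign", "LikelyBenign", "VUS", "LikelyPathogenic",
                   "Pathogenic")
tier_rank <- function(t) match(t, TIERS_ORDERED)

# random evidence-code sets for property tests
ALL_BASES <- c("PVS1", paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5),
               "BA1", paste0("BS", 1:4), paste0("BP", 1:7))
MODIFIABLE_STRENGTHS <- c("Supporting", "Moderate", "Strong", "VeryStrong")
random_code_set <- function(max_n = 6L) {
  n <- sample(0:max_n, 1L)
  if (n == 0L) return(list())
  lapply(seq_len(n), function(i) {
    base <- sample(ALL_BASES, 1L)
    if (base == "BA1" || stats::runif(1) < 0.5) parse_code(base)
    else parse_code(paste0(base, "_",
                           c(Supporting = "Sup", Moderate = "Mod",
                             Strong = "S", VeryStrong = "VS")[
                               sample(MODIFIABLE_STRENGTHS, 1L)]))
  })
}
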