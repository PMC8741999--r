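test_that("superposing a model on itself and on rigid copies gives zero RMSD", {
  ref <- generate_helix_pair(n_residues = 15, hinge_interval = c(5L, 8L), hinge_angle = 0, noise_sd = 0,
                             seed = 1)$reference
  sp <- kabsch_superpose(ref, ref)
  expect_lt(sp$global_rmsd, 1e-9)
  expect_true(all(sp$per_residue_rmsd < 1e-9))
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)

  moved <- rigid_move(ref, deg = 90, shift = c(5, 5, 5))
  sp2 <- kabsch_superpose(moved, ref)
  expect_lt(sp2$global_rmsd, 1e-9)
})

test_that("superposition errors on unusable inputs", {
  a <- make_structure(list(list("CA", "ALA", "A", 1, 0, 0, 0),
                           list("CA", "ALA", "A", 2, 1, 0, 0)))
  expect_error(kabsch_superpose(a, a), "at least 3")
  line <- make_structure(lapply(1:4, function(i)
    list("CA", "ALA", "A", i, i, 0, 0)))
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("Kabsch matches the rotation-grid brute-force oracle", {
  set.seed(123)
  for (i in 1:10) {
    n <- sample(4:6, 1)
    P <- random_points(n)
    Q <- P + matrix(stats::rnorm(3 * n, sd = 0.4), ncol = 3)
    expect_lt(abs(kabsch_points_rmsd(P, Q) - grid_rmsd_oracle(P, Q)), 1e-3)
  }
})

test_that("Kabsch agrees with an established least-squares fit", {
  set.seed(99)
  hp <- generate_helix_pair(n_residues = 20, hinge_interval = c(5L, 8L), seed = 4)
  sp <- kabsch_superpose(hp$mobile, hp$reference)
  xyz_fixed <- matrix(t(as.matrix(hp$reference[, c("x", "y", "z")])), nrow = 1)
  xyz_mob <- matrix(t(as.matrix(hp$mobile[, c("x", "y", "z")])), nrow = 1)
  # independent route: bio3d rigid-body fit over the same atom pairing
  idx <- which(hp$reference$atom_name %in% c("N", "CA", "C", "O"))
  rr <- bio3d::fit.xyz(xyz_fixed, xyz_mob, bio3d::atom2xyz(idx),
                       bio3d::atom2xyz(idx))
  rmsd_bio3d <- bio3d::rmsd(xyz_fixed, rr, bio3d::atom2xyz(idx),
                            bio3d::atom2xyz(idx))
  expect_equal(sp$global_rmsd, rmsd_bio3d, tolerance = 1e-4)
})

test_that("motile-region detection segments the RMSD profile", {
  flat <- setNames(rep(0.5, 40), 1:40)
  expect_equal(nrow(detect_motile_regions(flat, threshold = 1.0)), 0L)

  prof <- setNames(rep(0.2, 60), 1:60)
  prof[10:17] <- 3; prof[40:46] <- 2.5
  reg <- detect_motile_regions(prof, min_len = 5, threshold = 1.0)
  expect_equal(reg$start, c(10L, 40L))
  expect_equal(reg$end, c(17L, 46L))

  # short excursions below min_len are not regions
  prof2 <- setNames(rep(0.2, 30), 1:30)
  prof2[5:7] <- 3
  expect_equal(nrow(detect_motile_regions(prof2, min_len = 5,
                                          threshold = 1.0)), 0L)
})

test_that("generated hinge pairs yield one region containing the hinge", {
  hp <- generate_helix_pair(hinge_interval = c(20L, 30L), hinge_angle = 30,
                            noise_sd = 0.1, seed = 17)
  sp <- kabsch_superpose(hp$mobile, hp$reference)
  reg <- detect_motile_regions(sp$per_residue_rmsd)
  expect_equal(nrow(reg), 1L)
  expect_lte(reg$start, 20L)
  expect_gte(reg$end, 30L)
})

test_that("side-chain minimum distances use heavy atoms with CA fallback", {
  m <- make_structure(list(
    list("CA", "ALA", "A", 1, 0, 0, 0), list("CB", "ALA", "A", 1, 1, 0, 0),
    list("CA", "ALA", "A", 5, 9, 0, 0), list("CB", "ALA", "A", 5, 5, 0, 0),
    list("CA", "GLY", "A", 9, 0, 8, 0)))
  d <- sidechain_min_distance(m, "A:1", "A:5")
  expect_equal(as.numeric(d), 4.0)
  expect_false(attr(d, "fallback"))
  expect_equal(as.numeric(sidechain_min_distance(m, "A:1", "A:1")), 0.0)
  dg <- sidechain_min_distance(m, "A:1", "A:9")  # GLY: CA fallback, flagged
  expect_true(attr(dg, "fallback"))
  expect_equal(as.numeric(dg), sqrt(1 + 64))
  expect_error(sidechain_min_distance(m, "A:1", "B:1"), "no atoms")
})

test_that("neighbor shells respect the cutoff, exclusions and ordering", {
  m <- make_structure(list(
    list("CA", "ALA", "A", 10, 0, 0, 0), list("CB", "ALA", "A", 10, 0, 0, 1),
    list("CA", "ALA", "A", 11, 2, 0, 0), list("CB", "ALA", "A", 11, 2, 0, 1),
    list("CA", "ALA", "A", 20, 4, 0, 0), list("CB", "ALA", "A", 20, 4, 0, 1),
    list("CA", "ALA", "A", 30, 7, 0, 0), list("CB", "ALA", "A", 30, 7, 0, 1)))
  sh <- neighbor_shell(m, "A:10", cutoff = 5)
  expect_equal(sh$resseq, 20L)         # 4 A in, 7 A out, i+1 excluded
  expect_equal(nrow(neighbor_shell(m, "A:10", cutoff = 0)), 0L)
  # shell membership is monotone in the cutoff
  sizes <- vapply(c(1, 4.5, 8, 100), function(cc)
    nrow(neighbor_shell(m, "A:10", cutoff = cc)), 0L)
  expect_true(all(diff(sizes) >= 0))
})

test_that("average shell distance is the arithmetic mean of minima", {
  m <- make_structure(list(
    list("CB", "ALA", "A", 1, 0, 0, 0),
    list("CB", "ALA", "A", 10, 3, 0, 0),
    list("CB", "ALA", "A", 20, 0, 4, 0),
    list("CB", "ALA", "A", 30, 0, 0, 5)))
  expect_equal(avg_shell_distance(m, "A:1", list("A:10", "A:20", "A:30")), 4.0)
  expect_equal(avg_shell_distance(m, "A:1", list("A:10")), 3.0)
  expect_error(avg_shell_distance(m, "A:1", list()), "non-empty")
})

test_that("interface residues are those within the ligand cutoff", {
  # protein residues strung 10 A apart; a 3-atom ligand 4 A from residue 5
  prot <- unlist(lapply(1:8, function(i) list(
    list("CA", "ALA", "A", i, 10 * i, 0, 0),
    list("CB", "ALA", "A", i, 10 * i, 1.5, 0))), recursive = FALSE)
  lig <- list(list("P", "LIG", "B", 1, 54, 0, 0),
              list("O1", "LIG", "B", 1, 54.5, 0, 0),
              list("O2", "LIG", "B", 1, 54, 0.5, 0))
  both <- make_structure(c(prot, lig))
  got <- interface_residues(both, "B", cutoff = 5)
  expect_equal(got$resseq, 5L)
  far <- make_structure(c(prot, lapply(lig, function(a) {
    a[[5]] <- as.numeric(a[[5]]) + 1000; a })))
  expect_equal(nrow(interface_residues(far, "B", cutoff = 5)), 0L)
  expect_equal(nrow(interface_residues(both, "B", cutoff = 1e6)), 8L)
  expect_error(interface_residues(both, "Z"), "absent")
})

test_that("burial proxy separates core from peripheral residues", {
  g <- generate_globule(seed = 2)
  core <- burial_proxy(g$model, g$core)
  peri <- burial_proxy(g$model, g$periphery)
  expect_gt(core, peri)
  expect_gt(core, mechanism_config()$burial_cutoff)   # core counts as buried
  expect_lt(peri, mechanism_config()$burial_cutoff)
  lone <- make_structure(list(list("CB", "ALA", "A", 1, 0, 0, 0)))
  expect_equal(burial_proxy(lone, "A:1"), 0L)
})

test_that("template screening applies strict cutoffs and ranking", {
  cand <- data.frame(id = c("t1", "t2", "t3", "t4", "t5"),
                     identity = c(0.40, 0.36, 0.50, 0.80, 0.80),
                     resolution = c(2.0, 2.0, 2.6, 2.2, 1.9))
  out <- template_screen(cand)
  expect_equal(out$id, c("t5", "t4", "t1"))  # identity desc, resolution tiebreak
  expect_false("t2" %in% out$id)   # identity must exceed 0.36 strictly
  expect_false("t3" %in% out$id)   # resolution must be under 2.5 strictly
  expect_equal(template_screen(cand, resolution_max = 2.4)$id,
               c("t5", "t4", "t1"))
})

test_that("ddG classification uses a strict 1.6 kcal/mol threshold", {
  expect_true(ddg_classify(ddg_replicate_set("p.(Met117Ile)", mean = 4.11,
                                             sd = 0.63)))
  expect_false(ddg_classify(ddg_replicate_set("p.(Asn124Ile)", mean = 0.41,
                                              sd = 0.66)))
  expect_false(ddg_classify(ddg_replicate_set("x", mean = 1.6, sd = 0)))
})

test_that("formal side-chain charge deltas", {
  expect_equal(charge_delta("E", "K"), 2L)
  expect_equal(charge_delta("T", "M"), 0L)
  expect_equal(charge_delta("R", "H"), -1L)
  expect_equal(charge_delta("K", "E"), -2L)
  expect_error(charge_delta("X", "A"), "nonstandard")
})

test_that("mechanism assignment follows the stated precedence", {
  cfg <- mechanism_config()
  # interface membership wins even for a +2 charge change
  v1 <- assign_mechanism("missense", "p.(Glu638Lys)",
                         ddg = ddg_replicate_set("x", mean = -0.06, sd = 0.5),
                         in_interface = TRUE)
  expect_equal(v1$label, "interface_interaction")
  # destabilizing ddG -> stability
  v2 <- assign_mechanism("missense", "p.Thr629Met",
                         ddg = ddg_replicate_set("x", mean = 2.56, sd = 0.19))
  expect_equal(v2$label, "stability")
  # neutral, stable, non-interface -> nonconclusive
  v3 <- assign_mechanism("missense", "p.(Asn124Ile)",
                         ddg = ddg_replicate_set("x", mean = 0.41, sd = 0.66))
  expect_equal(v3$label, "nonconclusive")
  # charge-changing but buried residues fail the surface gate
  v4 <- assign_mechanism("missense", "p.(Arg453Gln)",
                         ddg = ddg_replicate_set("x", mean = 1.42, sd = 0.3),
                         buried = TRUE)
  expect_equal(v4$label, "nonconclusive")
  # proline introduced inside a helix counts as stability below threshold
  v5 <- assign_mechanism("missense", "p.(Gln147Pro)",
                         ddg = ddg_replicate_set("x", mean = 1.49, sd = 0.12),
                         in_helix = TRUE)
  expect_equal(v5$label, "stability")
  expect_equal(assign_mechanism("frameshift")$label, "LoF")
  expect_equal(assign_mechanism("nonsense")$label, "LoF")
})

test_that("burial can be derived from a model via the proxy gate", {
  g <- generate_globule(seed = 3)
  # place a charge-changing substitution at the core and at the periphery
  core_v <- assign_mechanism("missense",
                             sprintf("p.(Arg%dGln)", g$core$resseq),
                             model = g$model)
  peri_v <- assign_mechanism("missense",
                             sprintf("p.(Arg%dGln)", g$periphery$resseq),
                             model = g$model)
  expect_equal(core_v$label, "nonconclusive")
  expect_equal(peri_v$label, "electrostatic_surface")
})

test_that("PP3 derivation from mechanism verdicts", {
  stab <- assign_mechanism("missense", "p.Thr629Met",
                           ddg = ddg_replicate_set("x", mean = 2.56, sd = 0.19))
  code <- pp3_from_structure(stab)
  expect_equal(code$base, "PP3")
  expect_equal(code$applied_strength, "Supporting")
  noncon <- assign_mechanism("missense", "p.(Asn124Ile)",
                             ddg = ddg_replicate_set("x", mean = 0.41, sd = 0.66))
  expect_null(pp3_from_structure(noncon))
  expect_null(pp3_from_structure(assign_mechanism("nonsense")))
})
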