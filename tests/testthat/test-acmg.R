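test_that("evidence-code tokens parse across modifier dialects", {
  pm3 <- parse_code("PM3_VS")
  expect_equal(pm3$base, "PM3")
  expect_equal(pm3$applied_strength, "VeryStrong")
  expect_equal(pm3$direction, "pathogenic")

  pvs <- parse_code("PVS1")
  expect_equal(pvs$applied_strength, "VeryStrong")  # family default

  # _S always means Strong, even on a PVS/BS base (a downgrade)
  expect_equal(parse_code("PVS1_S")$applied_strength, "Strong")
  expect_equal(parse_code("BS1_Sup")$applied_strength, "Supporting")
  expect_equal(parse_code("BS1_Sup")$direction, "benign")

  expect_identical(parse_code("PP1_S"), parse_code("PP1_Strong"))
  expect_identical(parse_code("PP1_Sup"), parse_code("PP1_Supporting"))
  expect_identical(parse_code("PP1_M"), parse_code("PP1_Moderate"))
  expect_identical(parse_code("pm2_sup"), parse_code("PM2_Supporting"))

  expect_error(parse_code("PX9"), "unknown evidence code")
  expect_error(parse_code("PM3_Huge"), "modifier")
})

test_that("combine_evidence reproduces curated worked examples", {
  expect_equal(combine_evidence("PM2, PVS1, PP1_Sup"), "Pathogenic")
  expect_equal(combine_evidence("PM2, PP3"), "VUS")
  expect_equal(combine_evidence("BA1, PS2"), "Benign")
  expect_equal(combine_evidence("PM2, PM3_Strong, PP4"), "LikelyPathogenic")
  expect_equal(combine_evidence(list()), "VUS")
  # VeryStrong upgrade + benign-supporting evidence that must not conflict
  expect_equal(combine_evidence("BS1_Sup, PM3_VS, PP1_S, PS3_Sup"), "Pathogenic")
  # expert-panel LP combination: one Moderate with three Supporting
  expect_equal(combine_evidence("PM2, PM3_Supporting, PP3, PP4"),
               "LikelyPathogenic")
})

test_that("the combiner is permutation-invariant", {
  set.seed(42)
  for (i in 1:50) {
    codes <- random_code_set()
    if (length(codes) < 2) next
    shuffled <- codes[sample(length(codes))]
    expect_identical(combine_evidence(codes), combine_evidence(shuffled))
  }
})

test_that("curation of the transcribed cohort matches the printed tiers", {
  t2 <- classify_table(load_fixture("table2"))
  printed <- vapply(t2$after_curation, hlcur:::normalize_tier, "",
                    USE.NAMES = FALSE)
  disc <- paste(t2$gene, t2$protein)[t2$tier != printed]
  expect_equal(sum(t2$tier == printed), 26L)
  expect_setequal(disc, c("COL4A5 p.(Gly1220Asp)", "ACTG1 p.(Lys118Met)"))
  # both documented discordances land one tier below the printed call
  expect_true(all(t2$tier[t2$tier != printed] == "LikelyPathogenic"))
})

test_that("rows without evidence are flagged VUS", {
  tab <- data.frame(patient_id = "p", gene = "GJB2", cdna = "c.1A>G",
                    criteria = NA_character_, stringsAsFactors = FALSE)
  out <- classify_table(tab)
  expect_equal(out$tier, "VUS")
  expect_true(out$no_evidence)
})

test_that("structure-derived codes merge without duplicating bases", {
  tab <- data.frame(patient_id = "p", gene = "LARS2", cdna = "c.1886C>T",
                    criteria = "PM2, PM3, PP4", stringsAsFactors = FALSE)
  pp3 <- list(parse_code("PP3"))
  out <- classify_table(tab, extra_codes = list("c.1886C>T" = pp3))
  expect_equal(out$tier, "LikelyPathogenic")  # m2 p2 after merge
  # PP3 already present: merging again must not double-count
  tab$criteria <- "PM2, PP3"
  out2 <- classify_table(tab, extra_codes = list("c.1886C>T" = pp3))
  expect_equal(out2$tier, "VUS")
})

test_that("reclassification report reproduces the prior-assertion tally", {
  t2 <- load_fixture("table2")
  rec <- reclassification_report(t2)
  expect_equal(rec$n_prior_asserted, 16L)
  expect_equal(rec$n_changed, 11L)
  expect_equal(round(rec$percent_changed), 69)

  none <- data.frame(patient_id = "p", gene = "G", cdna = "c.1A>G",
                     clinvar = NA_character_, tier = "VUS",
                     stringsAsFactors = FALSE)
  rec0 <- reclassification_report(none, tier_col = "tier")
  expect_equal(rec0$n_prior_asserted, 0L)
  expect_true(rec0$undefined)
})

test_that("combiner agrees with the truth-table oracle on a sample", {
  set.seed(7)
  bases <- c("PVS1", "PS1", "PM1", "PP1", "BA1", "BS1", "BP1")
  for (i in 1:200) {
    ms <- sample(bases, sample(0:6, 1), replace = TRUE)
    expect_identical(combine_evidence(lapply(ms, parse_code)),
                     oracle_combine_bases(ms),
                     info = paste(ms, collapse = "+"))
  }
})
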