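mk_table <- function(genes, consequence = "missense", af = NA_real_,
                     zygosity = "het") {
  n <- length(genes)
  df <- data.frame(patient_id = "p1", gene = genes, transcript = "NM",
                   cdna = sprintf("c.%dA>G", seq_len(n)),
                   consequence = rep_len(consequence, n),
                   zygosity = rep_len(zygosity, n),
                   af_global = rep_len(af, n), stringsAsFactors = FALSE)
  class(df) <- c("variant_table", "data.frame")
  df
}

test_that("panel filtering keeps only in-panel genes", {
  panel <- gene_panel(c("GJB2", "MYO7A", "LARS2"))
  tab <- mk_table(c("GJB2", "MYO7A", "LARS2", sprintf("OFF%d", 1:7)))
  out <- filter_by_panel(tab, panel)
  expect_equal(nrow(out), 3L)
  expect_true(all(out$gene %in% panel$genes))
  expect_equal(nrow(filter_by_panel(out, panel)), 3L)   # identity on all-in-panel
  expect_equal(nrow(filter_by_panel(tab[0, ], panel)), 0L)
  expect_error(filter_by_panel(tab, gene_panel(character(0))), "empty")
})

test_that("consequence filtering keeps the disease-relevant classes", {
  tab <- mk_table(paste0("G", 1:6),
                  consequence = c("missense", "splice_site", "synonymous",
                                  "synonymous", "intronic", "nonsense"))
  out <- filter_by_consequence(tab)
  expect_equal(nrow(out), 3L)
  expect_false(any(out$consequence %in% c("synonymous", "intronic")))
  expect_true("splice_site" %in% out$consequence)
})

test_that("MAF ceilings are inheritance-aware and inclusive", {
  tab <- mk_table("GJB2", af = 0.009)
  expect_equal(nrow(filter_by_maf(tab, "autosomal_recessive")), 1L)
  expect_equal(nrow(filter_by_maf(tab, "autosomal_dominant")), 0L)
  # boundary is inclusive as the thresholds are stated
  expect_equal(nrow(filter_by_maf(mk_table("GJB2", af = 0.01),
                                  "autosomal_recessive")), 1L)
  expect_equal(nrow(filter_by_maf(mk_table("GJB2", af = 0.0100001),
                                  "autosomal_recessive")), 0L)
  # absent frequency cannot justify exclusion
  expect_equal(nrow(filter_by_maf(mk_table("GJB2", af = NA_real_),
                                  "autosomal_dominant")), 1L)
  # unknown model falls back to the looser recessive ceiling
  expect_equal(nrow(filter_by_maf(tab, NA_character_)), 1L)
})

test_that("filters compose order-invariantly and idempotently", {
  set.seed(5)
  coh <- generate_cohort(cohort_spec(n_patients = 6L, seed = 9L))
  tab <- coh$variants
  panel <- load_fixture("panel")
  cfg <- filter_config()
  perms <- list(c(1, 2, 3), c(3, 2, 1), c(2, 1, 3))
  apply_perm <- function(tab, ord) {
    fs <- list(function(t) filter_by_panel(t, panel),
               function(t) filter_by_consequence(t, cfg),
               function(t) filter_by_maf(t, "autosomal_recessive", cfg))
    for (i in ord) tab <- fs[[i]](tab)
    tab
  }
  keys <- lapply(perms, function(p) sort(paste(apply_perm(tab, p)$patient_id,
                                               apply_perm(tab, p)$cdna)))
  expect_identical(keys[[1]], keys[[2]])
  expect_identical(keys[[1]], keys[[3]])
  once <- filter_variants(tab, panel, "autosomal_recessive", cfg)
  twice <- filter_variants(once, panel, "autosomal_recessive", cfg)
  expect_identical(sort(paste(once$patient_id, once$cdna)),
                   sort(paste(twice$patient_id, twice$cdna)))
})

test_that("spiked causal variants always survive all three filters", {
  for (s in 1:3) {
    coh <- generate_cohort(cohort_spec(n_patients = 10L, seed = s))
    filtered <- filter_variants(coh$variants, load_fixture("panel"))
    kept <- paste(filtered$patient_id, filtered$cdna)
    expect_true(all(paste(coh$truth$patient_id, coh$truth$cdna) %in% kept),
                info = paste("seed", s))
  }
})
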