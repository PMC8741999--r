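# hlcur — hearing-loss variant curation with structural evidence

Molecular diagnosis of hereditary hearing loss means sifting tens of
thousands of exome variants down to a handful of candidates and then
defending a clinical classification for each one. `hlcur` implements that
workflow as a tested R package for curators and methodologists:

* **Filtering** — an in-silico deafness gene panel, disease-relevant
  consequence classes, and inheritance-aware minor-allele-frequency
  ceilings (MAF ≤ 0.01 recessive, ≤ 0.005 dominant, inclusive).
* **Classification** — strength-modified ACMG/AMP evidence codes
  (`PM3_VS`, `PP1_Sup`, `PVS1_S`, ...) parsed across the dialects expert
  panels actually write, and combined into
  Pathogenic / Likely Pathogenic / VUS / Likely Benign / Benign by
  categorical rules over evidence counted at applied strength
  (vs, s, m, p on the pathogenic side; BA1 stand-alone overriding all).
* **Structural triage** — missense variants assigned a mechanism by fixed
  precedence: loss of function → ligand-interface interaction →
  electrostatic surface (formal charge change *and* surface exposure) →
  stability (mean FoldX-style ΔΔG strictly above 1.6 kcal/mol, or a
  proline introduced/removed inside an annotated helix) → nonconclusive.
  A conclusive mechanism feeds PP3 back into the evidence set.
* **Geometry** — Kabsch superposition with per-residue backbone RMSD,
  motile-region detection, minimum side-chain heavy-atom distances,
  neighbor shells, interface detection at 5 Å, and a burial proxy.
* **Phenotype** — pure-tone averages (0.5/1/2/4 kHz), severity bins
  (moderate 41–70, severe 71–95, profound > 95 dB HL) and audiogram shape
  labels.
* **Synthetic data** — seeded generators for annotated cohorts with spiked
  causal variants and truth tables, pedigrees, two-conformation toy
  helices, and Gaussian ΔΔG replicate sets, so the whole pipeline is
  testable offline. Shipped fixtures transcribe a published 28-variant
  curation table and a 20-variant LARS2 (mitochondrial leucyl-tRNA
  synthetase) evaluation table.

## Worked example

Classify the shipped cohort table and summarize it, together with the
structural mechanism breakdown of the LARS2 evaluation table:

```r
library(hlcur)

t2 <- classify_table(load_fixture("table2"))
mech <- assign_mechanism_table(load_fixture("table3"))
summarize_cohort(load_fixture("table2"), n_cohort = 32,
                 mechanisms = mech$mechanism)
#> cohort: 32 patients, findings in 20 (62.5%)
#> variants: 28 (11 novel, 16 with prior ClinVar assertion)
#> reclassified: 11/16 (69%)
#> mechanism breakdown (missense):
#>   stability               7 (41%)
#>   electrostatic_surface   3 (18%)
#>   interface_interaction   3 (18%)
#>   nonconclusive           4 (24%)
```

Twenty of 32 patients carry at least one reportable variant (62.5%); of
the 16 variants with a prior ClinVar assertion, 11 (69%) change tier under
expert-panel curation. Over the 17 LARS2 missense variants, stability is
the dominant structural mechanism (7/17, 41%) and 4 (24%) stay
nonconclusive.

One variant end to end — a destabilizing substitution earns supporting
computational evidence:

```r
v <- assign_mechanism("missense", "p.Thr629Met",
                      ddg = ddg_replicate_set("p.Thr629Met",
                                              mean = 2.56, sd = 0.19))
v
#> mechanism: stability
pp3_from_structure(v)
#> PP3 [pathogenic, Supporting]
combine_evidence("PM2, PM3_S, PP1_Sup, PP4")
#> [1] "LikelyPathogenic"
```

Conformational mobility on a synthetic two-state helix:

```r
hp <- generate_helix_pair(seed = 42)          # mobile segment at 20-30
sp <- kabsch_superpose(hp$mobile, hp$reference)
sp
#> superposition over 400 atoms: global RMSD 0.358 A (100 residues)
detect_motile_regions(sp$per_residue_rmsd)
#>   start end
#> 1    20  30
```

The detector recovers the generated mobile segment exactly: residues
20–30 stand out of the noise floor after the global backbone fit.

See `vignettes/hlcur-methods.Rmd` for the combination rules, the mechanism
precedence and gates, geometry conventions, and what the generators do and
do not emulate.

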