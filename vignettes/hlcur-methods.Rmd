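---
title: "Curation methods: evidence combination and structural triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curation methods: evidence combination and structural triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlcur)
```

hlcur implements a multistep interpretation workflow for sensorineural
hearing-loss variants: reduce an annotated exome-derived variant list with a
deafness gene panel and frequency/consequence rules, combine
strength-modified ACMG/AMP evidence codes into the five-tier clinical
classification, and triage missense variants into structural mechanism
classes from protein-model geometry and folding-energy predictions. This
vignette documents the model choices, the tunable parameters, and what the
synthetic-data generators do and do not emulate.

## Candidate filtering

Three set-intersection filters reduce an annotated variant table:

* **Panel** — only genes on an in-silico deafness panel are retained. The
  shipped panel (`load_fixture("panel")`) is a synthetic stand-in list of 62
  hereditary hearing-loss genes; a production panel (e.g. a 183-gene
  diagnostic panel) is supplied as a one-symbol-per-line file.
* **Consequence** — missense, nonsense, frameshift, in-frame indel and
  splice-site classes are kept; synonymous and intronic calls are decoys.
* **Minor allele frequency** — inclusive ceilings of 0.01 (recessive) and
  0.005 (dominant). A missing frequency never excludes a variant (absence of
  evidence is not evidence of rarity in the exclusion direction); such rows
  are kept and flagged in the stage log. When a case's inheritance model is
  unknown the looser recessive ceiling applies, to avoid false exclusion.

Because each filter is a pure row predicate, composition is order-invariant
and idempotent; the test suite asserts both. Row-count conservation
(input = kept + excluded) is logged at every stage.

## Evidence combination

Evidence arrives as ACMG/AMP criterion tokens with optional expert-panel
strength modifiers, in several dialects (`PM3_VS`, `PM3_Strong`, `PP1_Sup`,
`PP1_Supporting`, ...). `parse_code()` normalizes the dialects; `_S` always
means *Strong* — on a PVS base it is a downgrade, never "Supporting".

`combine_evidence()` counts codes at their *applied* strengths into buckets
(very strong / strong / moderate / supporting on the pathogenic side;
stand-alone / strong / supporting on the benign side) and applies
categorical combination rules in the Richards (2015) style, with three
expert-panel-usage extensions this package adopts as its reading of
hearing-loss panel practice:

1. a code upgraded to VeryStrong (e.g. `PM3_VS`, `PP1_VS`) counts exactly
   like PVS1 — without this reading, several curated pathogenic calls in
   the shipped cohort table are unreachable;
2. one Moderate plus three Supporting reaches Likely Pathogenic (the
   classic rule demands four Supporting); the LARS2 evaluation table's
   `PM2, PM3_Supporting, PP3, PP4` rows are Likely Pathogenic only under
   this combination;
3. two VeryStrong codes reach Pathogenic, and VeryStrong plus one
   Supporting reaches Likely Pathogenic (SVI-style completions that keep
   the rule set monotone).

Benign evidence whose own weight does not reach Likely Benign does **not**
force VUS: the cohort table contains Pathogenic rows carrying `BS1_Sup`.
BA1 is absolute and overrides everything. If both a pathogenic and a benign
combination are simultaneously met the verdict is VUS.

The combiner is permutation-invariant and monotone by construction
(counting); the suite checks it against an exhaustive, independently written
truth-table oracle over all multisets of up to six default-strength codes,
and property-tests monotonicity and upgrade coherence on random
strength-modified sets. The categorical rules are used rather than the
Tavtigian point system because the curated tables this package reproduces
apply rule-style criteria strings.

Two cohort-table rows (ACTG1 p.(Lys118Met) and COL4A5 p.(Gly1220Asp)) do
not reach their printed Pathogenic call under any standard combination
reading (both stop at Likely Pathogenic); the engine reports them as
discordant by name rather than special-casing them.

Reclassification against prior database assertions treats dual assertions
("Pathogenic/Likely pathogenic") and conflicting interpretations as changed
whenever curation yields any single tier; identical single tiers are
unchanged. On the shipped cohort table this reproduces the 11/16 (69%)
reclassification rate either from the transcribed post-curation column or
from the engine's own tiers (one row swaps in, one out, between the two
routes).

## Structural mechanism triage

For missense variants, `assign_mechanism()` applies a fixed precedence:

1. **LoF** — nonsense/frameshift consequences (handled upstream by PVS1).
2. **Interface interaction** — the residue belongs to the ligand-interface
   set. Interfaces are detected as protein residues with any heavy atom
   within 5.0 Å of a ligand-chain heavy atom, the same convention used to
   fix tRNA-contacting residues during force-field optimization.
3. **Electrostatic surface** — the substitution changes the formal
   side-chain charge (Asp/Glu −1, Lys/Arg +1, His 0) *and* the residue is
   surface-exposed. The exposure gate exists because a charge-changing but
   core-facing substitution perturbs packing, not the surface potential;
   the shipped evaluation table labels exactly such a buried
   arginine-to-glutamine row nonconclusive while the exposed
   charge-changers are electrostatic.
4. **Stability** — the mean predicted folding free-energy change (ΔΔG,
   kcal/mol, mean of five force-field replicas) is *strictly* above
   1.6 kcal/mol, or the substitution introduces/removes a proline inside an
   annotated helix. The proline rule is needed because a
   glutamine-to-proline row with mean ΔΔG 1.49 is curated as a stability
   effect: a helix-breaking proline destabilizes locally even when the
   global energy change sits under the threshold. Helix annotations are an
   input (a per-residue secondary-structure string), never computed here.
5. **Nonconclusive** otherwise.

Burial is either an annotation (as transcribed in the shipped evaluation
table) or derived from a model by `burial_proxy()`: the count of heavy
atoms of other residues within 8 Å of the side-chain centroid. The default
buried/exposed cutoff (45 atoms) was calibrated once on the synthetic
globule generator so that its core residue counts as buried and its
peripheral residue as exposed; it is a config parameter
(`mechanism_config()`), not a constant.

A conclusive mechanism (stability, electrostatic, interface) contributes
PP3 at Supporting strength to the evidence set; nonconclusive and LoF
verdicts contribute nothing (LoF is PVS1 territory and is not
double-counted). BP4 is never emitted automatically — an absent structural
signal is not evidence of benignity.

## Geometry conventions

* **Superposition** is the Kabsch least-squares rigid fit (SVD, reflection
  excluded) over backbone atoms N, CA, C, O paired by author residue
  number; no sequence alignment is performed, since paired conformations of
  the same model share numbering. Per-residue RMSD is computed over each
  residue's paired backbone atoms after the global fit.
* **Motile regions** are maximal runs of at least 5 consecutive residues
  with per-residue RMSD above a threshold; the default `"auto"` threshold
  is profile mean + 2 SD. The run length and threshold rule are this
  package's choice — published analyses report the resulting intervals, not
  a numeric rule.
* **Side-chain distance** between two residues is the minimum over
  heavy-atom pairs, side chain meaning heavy atoms excluding N, CA, C, O
  (and OXT); glycine falls back to CA with a flag. The average distance
  from a center to a shell of partners is the arithmetic mean of
  per-partner minima. Published per-residue contact averages do not state
  their atom-level convention; minimum-heavy-atom is this package's
  convention, and external-model comparisons should carry a tolerance of a
  few tenths of an Å for it.
* **Template screening** keeps homology-modeling candidates with sequence
  identity strictly above 0.36 and resolution strictly below 2.5 Å (a
  2.4 Å variant of the cutoff is config-accessible), ranked by identity
  then resolution.
* Residue addressing is 1-based author numbering throughout, with
  insertion codes preserved; residues absent from a model are flagged and
  skipped rather than erroring, since regions without template coverage are
  not analyzable.

## Synthetic data: what it emulates, and what it does not

`generate_cohort()` emulates the study conditions of a 32-proband WES
cohort: a deafness panel, a recessive/dominant mix, causal variants spiked
at a 62.5% case rate whose evidence codes are verified at generation to
combine to the planned tier, and rare background variants with
Beta(0.2, 5) allele frequencies plus synonymous/intronic decoys. Recessive
spikes are biallelic (homozygous, or an in-trans heterozygous pair with
distinct parental origins). Pedigrees are emitted consistent with each
plan. It does **not** simulate sequencing reads, calling error, population
structure, or genome-scale variant counts — the published reduction from
roughly 90,000 variants per exome to 1–10 candidates requires real WES
data and is out of desk scale; the filter properties are exercised on the
synthetic cohort instead.

`generate_helix_pair()` builds an ideal α-helix backbone (1.5 Å rise,
100°/residue, CB pseudo-side-chains) in two conformations. The mobile
segment is produced by rotating the hinge-interval residues rigidly about
the helix axis by the hinge angle, leaving the flanks identical, then
adding Gaussian coordinate noise (default 0.1 Å). A rigid arm bend was
deliberately not used: bending everything downstream of a hinge displaces
the whole arm, and after a global superposition the per-residue RMSD signal
is no longer localized at the mobile segment — whereas the conformational
comparisons this emulates show localized high-RMSD loops with superposable
flanks. Parameter recovery (detected interval vs. generated interval,
Jaccard ≥ 0.8 over seeded replicates) is part of the acceptance suite.
Passing these tests shows the detector recovers *localized* mobility under
the stated noise; it says nothing about domain-scale hinge motions or real
side-chain rotamers.

`generate_ddg_sets()` draws Normal(μ, σ) replicas (five by default,
matching the force-field protocol). Published tables often carry only
mean ± SD; `ddg_replicate_set()` therefore supports a summary form to
which replica-level operations degrade gracefully.

All generators are pure functions of (spec, seed) and restore the caller's
RNG state. Fixture files transcribing the published tables are
checksum-pinned (`verify_fixtures()`).

## Numerical and degenerate-input choices

* Sample (n−1) standard deviation for ddG replica sets (the published
  footnote reports mean ± SD of five replicas without naming the
  estimator).
* ΔΔG threshold comparisons are strict (`> 1.6`), as is template identity
  (`> 0.36`) and resolution (`< 2.5`), following the stated wording;
  MAF ceilings are inclusive (`≤`).
* Kabsch refuses fewer than three atom pairs and collinear point sets (the
  rotation is not uniquely defined); reflections are excluded by the sign
  correction on the smallest singular vector.
* PDB altloc policy: highest occupancy wins, ties go to the first record
  encountered. Only the first MODEL block is read. Parsing is
  fixed-column (wwPDB v3.3); a malformed ATOM/HETATM line fails with its
  line number rather than being skipped.
* Severity bins for the pure-tone average (0.5/1/2/4 kHz mean) follow the
  printed integer bounds (moderate 41–70, severe 71–95, profound > 95
  dB HL) with non-integer averages assigned to the lower bin up to the
  next bound; below 41 dB HL is reported as `below_range` rather than
  forced into a bin. Audiogram shapes use a 15 dB slope/flatness
  criterion (config-exposed) — the shape classes are standard but carry
  no published numeric rule; precedence high-frequency → low-frequency →
  U-shaped → flat makes the rule set a partition.
* Whether published pure-tone averages used better-ear or binaural
  thresholds is unstated; the audiogram reader keeps the `ear` column so
  either convention can be selected upstream.

## Problem sizes used in the test suite

The acceptance suite runs at desk scale: the 28-row cohort table and
20-row evaluation table, 100 random ≤ 6-point superposition instances
against a rotation-grid oracle, 20 seeded helix-pair replicates, the
exhaustive ≤ 6-code truth table (1,716 multisets) and 10,000 random
strength-modified code sets for the combiner properties. These sizes were
chosen as the smallest that exercise every rule branch and give stable
pass/fail behavior for the stochastic checks.

## Known limitations

* ΔΔG values are consumed, never computed: the force-field energy model is
  out of scope, as are mutant rotamer building (so published
  mutant-side-chain distances are not reproduced), continuous
  Poisson–Boltzmann electrostatics (replaced by the formal-charge
  heuristic), and homology-model construction/QC.
* Evidence codes are inputs; the engine does not derive PM2 from
  frequencies or PVS1 from transcript context. The single derived code is
  the structure-based PP3.
* Segregation checking is a consistency test, not a likelihood (no LOD
  scores); X-linked handling is limited to hemizygote support.
* mmCIF and VCF ingestion are out of scope; the contracts are PDB and
  annotated TSV.
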