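Package: hlcur
Title: Hearing-Loss Variant Curation with Structural Evidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a multistep variant-interpretation
    workflow for sensorineural hearing loss. Annotated per-patient variant
    tables are reduced with an in-silico deafness gene panel, consequence-class
    and inheritance-aware minor-allele-frequency filters; ACMG/AMP evidence
    codes carrying hearing-loss expert-panel strength modifiers are parsed and
    combined into the five-tier classification; missense variants are triaged
    into structural mechanism classes (stability, electrostatic surface,
    ligand-interface interaction) from FoldX-style ddG replicate tables,
    formal-charge deltas and protein-model geometry (Kabsch superposition,
    per-residue RMSD motile regions, side-chain distance shells, interface
    detection); and cohort curation reports are emitted. Seeded generators
    produce synthetic cohorts, pedigrees, two-conformation toy helices and
    ddG replicate sets so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
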