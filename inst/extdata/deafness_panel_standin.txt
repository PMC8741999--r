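# Synthetic stand-in deafness gene panel (one HGNC symbol per line).
# A reduced list for testing; covers the 16 genes with findings in the
# transcribed cohort plus common hereditary hearing-loss genes.
ACTG1
ADGRV1
BSND
CABP2
CDH23
CEACAM16
CIB2
CLDN14
CLRN1
COCH
COL11A1
COL11A2
COL2A1
COL4A3
COL4A4
COL4A5
DFNA5
DIAPH1
EDNRB
ESPN
EYA1
EYA4
GJB2
GJB6
GRXCR1
GSDME
ILDR1
KCNQ4
LARS2
LOXHD1
MARVELD2
MITF
MYH14
MYH9
MYO15A
MYO6
MYO7A
OTOA
OTOF
OTOG
OTOGL
PAX3
PCDH15
POU3F4
POU4F3
PTPRQ
RDX
SERPINB6
SIX1
SLC26A4
SOX10
STRC
TECTA
TMC1
TMPRSS3
TPRN
TRIOBP
USH1C
USH1G
USH2A
WFS1
WHRN
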