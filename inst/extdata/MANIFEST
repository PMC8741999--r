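cc5a9b16f43cb433bd03cb30db6b5099  table2_variants.tsv
19f9ba4b68040017938a8277b4d36674  table3_lars2.tsv
cdc248e2da859e69095b9bd42a82b816  lars2_domains.tsv
0d9a730284f8fe861ccffb3b0fb4584d  deafness_panel_standin.txt
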