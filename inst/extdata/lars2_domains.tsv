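order	region	kind
1	HIGH_motif	motif
2	catalytic	domain
3	editing	domain
4	leucine_specific	domain
5	KMSKS_motif	motif
6	anticodon	domain
7	C_terminal	domain
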