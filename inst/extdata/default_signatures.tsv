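signature_type	signature_name	gene
cell	M2	CD163
cell	M2	MRC1
cell	M2	C1QA
cell	M2	C1QB
cell	M1	CD86
cell	M1	MSR1
cell	mast	TPSAB1
cell	B	CD19
pathway	TLR	TLR1
pathway	TLR	TLR4
pathway	complement	C7
pathway	complement	C1QA
pathway	complement	C2
pathway	complement	C1R
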