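gene	position	major	minor	aa_major	aa_minor	rflp	maf	context_start_codon	context_seq
pBD1	171	A	G			BstNI	0.177	57	CCAGGT
pBD4	65	G	A	R	K	EcoRV	0.451	22	AGATATCAT
pBD113	114	A	G				0.029	38	GCA
pBD114	186	G	A				0.09	62	CTG
pBD115	144	A	T	Q	H		0.057	48	CAA
pBD115	291	G	A				0.043	97	ACG
pBD121	96	G	A			PciI	0.2	32	CCGCATGTT
pBD133	196	A	C	K	Q		0.043	66	AAG
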