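species	chromosome	anchor_up	anchor_up_alt	anchor_down	pos_up	pos_down
pig	SSC7	PGK2		TFAP2D	9e+05	1500000
pig	SSC14	pBD135		pBD131	1e+06	1081999
pig	SSC15	AGPAT5		SPATA4	9e+05	1500000
pig	SSC17	ZCCHC3	TRIB3	BCL2L1	9e+05	1600000
human	HSA6	PGK2		TFAP2D	9e+05	1500000
human	HSA8	AGPAT5		SPATA4	9e+05	1600000
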