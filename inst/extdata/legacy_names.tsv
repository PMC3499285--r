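gene	nearest_human	keep_name
pBD1	DEFB4	TRUE
pBD2	DEFB1	TRUE
pBD3	DEFB103	TRUE
pBD4	DEFB110	TRUE
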