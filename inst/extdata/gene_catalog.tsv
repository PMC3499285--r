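gene	number	status	pseudo
pBD105	105	new	FALSE
pBD106	106	new	FALSE
pBD112	112	new	FALSE
pBD113	113	new	FALSE
pBD115	115	new	FALSE
pBD116	116	new	FALSE
pBD118	118	new	FALSE
pBD119	119	new	FALSE
pBD122	122	new	FALSE
pBD123	123	new	FALSE
pBD124	124	new	FALSE
pBD128	128	new	FALSE
pBD130	130	new	FALSE
pBD131	131	new	FALSE
pBD133	133	new	FALSE
pBD134	134	new	FALSE
pBD135	135	new	FALSE
pBD1	1	reported	FALSE
pBD2	2	reported	FALSE
pBD3	3	reported	FALSE
pBD4	4	reported	FALSE
pBD104	104	reported	FALSE
pBD108	108	reported	FALSE
pBD114	114	reported	FALSE
pBD121	121	reported	FALSE
pBD125	125	reported	FALSE
pBD129	129	reported	FALSE
pBD117	117	partial_psi	TRUE
pBD127	127	partial_psi	TRUE
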