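enzyme	site
BstNI	CCWGG
EcoRV	GATATC
PciI	ACATGT
EcoRI	GAATTC
BamHI	GGATCC
HindIII	AAGCTT
TaqI	TCGA
MseI	TTAA
AluI	AGCT
HaeIII	GGCC
RsaI	GTAC
DdeI	CTNAG
HinfI	GANTC
Sau3AI	GATC
MspI	CCGG
NlaIII	CATG
ApoI	RAATTY
AvaI	CYCGRG
BsrGI	TGTACA
NcoI	CCATGG
NdeI	CATATG
PstI	CTGCAG
SmaI	CCCGGG
XbaI	TCTAGA
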