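species	symbol
human	DEFB110
human	DEFB112
human	DEFB113
human	DEFB114
human	DEFB133
human	DEFB1
human	DEFB4
human	DEFB103
human	DEFB104
human	DEFB105
human	DEFB106
human	DEFB107
human	DEFB130
human	DEFB131
human	DEFB132
human	DEFB134
human	DEFB135
human	DEFB136
human	DEFB137
human	DEFB115
human	DEFB116
human	DEFB118
human	DEFB119
human	DEFB121
human	DEFB123
human	DEFB124
human	DEFB125
human	DEFB126
human	DEFB127
human	DEFB128
human	DEFB129
human	DEFB132
cattle	BBD4
cattle	BBD5
cattle	BBD7
cattle	BBD10
cattle	BBD103A
cattle	BBD103B
cattle	BBD119
cattle	BBD122
cattle	BBD122A
cattle	BBD123
cattle	BBD124
cattle	BBD300
cattle	EBD
cattle	TAP
cattle	LAP
pig	pBD1
pig	pBD2
pig	pBD3
pig	pBD4
pig	pBD104
pig	pBD108
pig	pBD114
pig	pBD123
pig	pBD125
pig	pBD129
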