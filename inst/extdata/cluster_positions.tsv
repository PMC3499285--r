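species	gene	chromosome	start	end	strand	note
pig	pBD133	SSC7	1e+06	1001999	+	
pig	pBD114	SSC7	1040000	1041999	+	
pig	pBD113	SSC7	1080000	1081999	+	
pig	pBD4	SSC7	1120000	1121999	+	
pig	pBD112	SSC7	1160000	1161999	+	
pig	pBD135	SSC14	1e+06	1001999	+	
pig	pBD134	SSC14	1040000	1041999	+	
pig	pBD131	SSC14	1080000	1081999	+	
pig	pBD105	SSC15	1e+06	1001999	+	
pig	pBD106	SSC15	1040000	1041999	+	
pig	pBD104	SSC15	1080000	1081999	+	
pig	pBD1	SSC15	1120000	1121999	+	
pig	pBD2	SSC15	1160000	1161999	+	
pig	pBD130	SSC15	1200000	1201999	+	
pig	pBD129	SSC17	1e+06	1001999	+	
pig	pBD128	SSC17	1040000	1041999	+	
pig	pBD127	SSC17	1080000	1081999	+	
pig	pBD115	SSC17	1120000	1121999	+	
pig	pBD124	SSC17	1160000	1161999	+	
pig	pBD123	SSC17	1200000	1201999	+	
pig	pBD122	SSC17	1240000	1241999	+	
pig	pBD121	SSC17	1280000	1281999	+	
pig	pBD119	SSC17	1320000	1321999	+	
pig	pBD118	SSC17	1360000	1361999	+	
pig	pBD117	SSC17	1400000	1401999	+	
pig	pBD116	SSC17	1440000	1441999	+	
pig	pBD3	unplaced	NA	NA	+	inferred:SSC15;contig:NW_003613575.1
pig	pBD108	unplaced	NA	NA	+	not in printed cluster lists
pig	pBD125	unplaced	NA	NA	+	not in printed cluster lists
human	DEFB133	HSA6	1e+06	1001999	+	
human	DEFB114	HSA6	1040000	1041999	+	
human	DEFB113	HSA6	1080000	1081999	+	
human	DEFB110	HSA6	1120000	1121999	+	
human	DEFB112	HSA6	1160000	1161999	+	
human	DEFB105	HSA8	1e+06	1001999	+	
human	DEFB106	HSA8	1040000	1041999	+	
human	DEFB104	HSA8	1080000	1081999	+	
human	DEFB4	HSA8	1120000	1121999	+	
human	DEFB1	HSA8	1160000	1161999	+	
human	DEFB103A	HSA8	1200000	1201999	+	
human	DEFB103B	HSA8	1240000	1241999	+	
human	DEFB130	HSA8	1280000	1281999	+	
human	DEFB135	HSA8	1320000	1321999	+	
human	DEFB134	HSA8	1360000	1361999	+	
human	DEFB131	HSA8	1400000	1401999	+	
human	DEFB129	HSA20	1e+06	1001999	+	
human	DEFB128	HSA20	1040000	1041999	+	
human	DEFB127	HSA20	1080000	1081999	+	
human	DEFB126	HSA20	1120000	1121999	+	
human	DEFB125	HSA20	1160000	1161999	+	
human	DEFB124	HSA20	1200000	1201999	+	
human	DEFB123	HSA20	1240000	1241999	+	
human	DEFB122	HSA20	1280000	1281999	+	
human	DEFB121	HSA20	1320000	1321999	+	
human	DEFB119	HSA20	8e+06	8001999	+	
human	DEFB118	HSA20	8040000	8041999	+	
human	DEFB117	HSA20	8080000	8081999	+	
human	DEFB116	HSA20	8120000	8121999	+	
human	DEFB115	HSA20	8160000	8161999	+	
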