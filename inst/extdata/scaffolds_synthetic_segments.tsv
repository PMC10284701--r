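trna_id	family	segment	start	end	canonical_labels
tS_scaffold	Ser	acceptor5	0	7	1,2,3,4,5,6,7
tS_scaffold	Ser	D-arm	7	26	8,9,10,11,12,13,14,15,16,17,18,19,20,21,22,23,24,25,26
tS_scaffold	Ser	anticodon-stem5	26	31	27,28,29,30,31
tS_scaffold	Ser	anticodon-loop	31	38	32,33,34,35,36,37,38
tS_scaffold	Ser	anticodon-stem3	38	43	39,40,41,42,43
tS_scaffold	Ser	V-region	43	57	V01,V02,V03,V04,V05,V06,V07,V08,V09,V10,V11,V12,V13,V14
tS_scaffold	Ser	T-stem5	57	62	49,50,51,52,53
tS_scaffold	Ser	T-loop	62	69	54,55,56,57,58,59,60
tS_scaffold	Ser	T-stem3	69	74	61,62,63,64,65
tS_scaffold	Ser	acceptor3	74	81	66,67,68,69,70,71,72
tS_scaffold	Ser	discriminator	81	82	73
tR_scaffold	Arg	acceptor5	0	7	1,2,3,4,5,6,7
tR_scaffold	Arg	D-arm	7	24	8,9,10,11,12,13,14,15,16,17,18,19,20,21,22,23,24
tR_scaffold	Arg	anticodon-stem5	24	29	27,28,29,30,31
tR_scaffold	Arg	anticodon-loop	29	36	32,33,34,35,36,37,38
tR_scaffold	Arg	anticodon-stem3	36	41	39,40,41,42,43
tR_scaffold	Arg	V-region	41	46	V01,V02,V03,V04,V05
tR_scaffold	Arg	T-stem5	46	51	49,50,51,52,53
tR_scaffold	Arg	T-loop	51	58	54,55,56,57,58,59,60
tR_scaffold	Arg	T-stem3	58	63	61,62,63,64,65
tR_scaffold	Arg	acceptor3	63	70	66,67,68,69,70,71,72
tR_scaffold	Arg	discriminator	70	71	73
tG_scaffold	Gly	acceptor5	0	7	1,2,3,4,5,6,7
tG_scaffold	Gly	D-arm	7	24	8,9,10,11,12,13,14,15,16,17,18,19,20,21,22,23,24
tG_scaffold	Gly	anticodon-stem5	24	29	27,28,29,30,31
tG_scaffold	Gly	anticodon-loop	29	36	32,33,34,35,36,37,38
tG_scaffold	Gly	anticodon-stem3	36	41	39,40,41,42,43
tG_scaffold	Gly	V-region	41	46	V01,V02,V03,V04,V05
tG_scaffold	Gly	T-stem5	46	51	49,50,51,52,53
tG_scaffold	Gly	T-loop	51	58	54,55,56,57,58,59,60
tG_scaffold	Gly	T-stem3	58	63	61,62,63,64,65
tG_scaffold	Gly	acceptor3	63	70	66,67,68,69,70,71,72
tG_scaffold	Gly	discriminator	70	71	73
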