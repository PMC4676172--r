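patient	event	time	sex	age	grade	hbv_pre	hbv_post	cirrhosis
HCC1	1	8	M	48	3	1	0	1
HCC2	1	19	M	43	2	1	0	1
HCC3	1	14.5	M	42	3	1	0	1
HCC4	1	6.5	M	59	2	1	1	0
HCC5	1	18	M	67	2	0	0	1
HCC6	1	1.5	M	41	3	1	0	1
HCC8	1	11	M	42	3	1	0	1
HCC10	1	6	M	59	3	1	0	1
HCC11	1	16	F	57	2.5	0	0	1
HCC-C2	0	24	M	55	1.5	1	0	1
HCC-C6	0	24	M	51	2	1	0	1
HCC-C8	0	24	M	64	1	1	1	1
HCC-C9	0	24	M	40	2	1	NA	1
HCC-C11	0	24	M	62	1	1	0	1
HCC-C12	0	24	M	40	2.5	1	1	1
HCC-C13	0	24	M	49	1.5	1	0	1
HCC-C14	0	24	M	59	2	1	NA	1
HCC-C15	0	24	M	49	2	1	0	1
HCC-C16	0	24	M	49	2.5	1	NA	1
HCC-C18	0	24	M	57	1	1	0	1
HCC-C19	0	24	M	41	2.5	1	1	1
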