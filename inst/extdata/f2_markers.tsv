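population	marker	dom_AA	dom_Aa	dom_aa	rec_AA	rec_Aa	rec_aa
NGB1238xN24	ZFP	30	47	0	0	1	30
NGB1238xN24	Upl	32	43	2	0	5	26
NGB1238xN24	RibL13l	31	46	0	0	1	30
NGB1238xN24	AUXfp	33	43	1	0	4	27
NGB1238xN24	PrOx	35	40	2	1	6	24
NGB1238xN24	sdhFP	33	42	2	1	8	22
NGB1238xN24	IPD3:c319del	30	47	0	0	0	31
NGB1238xN24	PsC908p622	23	42	12	12	16	3
NGB1238xN24	PsC8268p528	26	39	12	9	19	2
SGExN24	RibL13l	7	11	0	0	0	9
SGExN24	AUXfp	4	13	1	0	1	8
SGExN24	IPD3:c319del	7	11	0	0	0	9
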