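name	motif
MboII	GAAGA
Tru1I	TTAA
BssECI	CCNNGG
BtsCI	GGATG
Hpy166II	GTNNAC
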