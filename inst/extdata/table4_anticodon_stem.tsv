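stem	Met	Ini	kIle
GGG,CCC	2	3849	1
AGG,CCU	1	522	1
AGG,UCU	6	34	0
GGG,UCC	0	18	0
CGG,CCG	869	0	974
UCA,UGA	405	0	0
GCA,UGC	369	0	0
GGA,UCC	335	0	583
CGA,UCG	213	0	654
GGA,CCC	114	0	75
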