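prior	Met	Ini	kIle
Met	1055	0	51
Ini	0	1824	0
kIle	11	0	977
Unspecified	1696	2614	1689
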