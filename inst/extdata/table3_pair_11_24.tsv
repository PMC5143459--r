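pair	Met	Ini	kIle
A:U	0	4430	0
C:G	2759	3	2706
G:C	0	3	0
-:-	1	1	0
U:A	1	1	8
U:G	1	0	2
C:A	0	0	1
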