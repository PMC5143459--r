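pair	Met	Ini	kIle
C:A	2	3392	1
C:U	0	626	0
U:U	1	207	1
C:C	0	90	2
U:A	2	63	1
A:A	0	39	2
U:G	1	9	2
G:A	0	7	0
U:C	1	3	3
A:C	0	1	6
A:G	0	1	1
G:U	1371	0	103
G:C	1287	0	2511
C:G	66	0	77
A:U	30	0	6
S:C	1	0	0
G:G	0	0	1
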