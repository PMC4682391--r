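amino_acid	aa	high_pct	low_pct
Ala	A	7	6.8
Arg	R	4.2	4.8
Asn	N	4.8	4.5
Asp	D	5.2	5.9
Cys	C	2.6	1.7
Glu	E	3.9	4.2
Gln	Q	5.7	7
Gly	G	7.8	6.6
His	H	2.1	2.3
Ile	I	4.7	5.3
Leu	L	8.2	9
Lys	K	5.7	6.4
Met	M	1.7	2.3
Phe	F	3.5	4
Pro	P	4.9	4.7
Ser	S	8.6	6.7
Thr	T	6.7	6
Trp	W	1.7	1.4
Tyr	Y	3.9	3.5
Val	V	7	6.9
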