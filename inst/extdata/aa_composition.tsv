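analyte	fraction	glucose	methanol_glycerol
Asx	bound	30.2	48.8
Ala	bound	20.2	32.1
Arg	bound	25.9	29.6
Cys	bound	4.56	5.59
Glx	bound	68.0	87.0
Gly	bound	11.5	18.7
His	bound	7.33	11.9
Ile	bound	10.6	17.8
Leu	bound	22.6	36.0
Lys	bound	24.5	37.5
Met	bound	4.33	5.34
Phe	bound	12.9	20.0
Ser	bound	19.0	25.9
Thr	bound	19.3	28.2
Tyr	bound	8.89	17.3
Val	bound	15.7	26.4
Asx	free	2.91	5.42
Ala	free	1.02	0.90
Arg	free	12.1	11.1
Glx	free	29.4	22.3
His	free	0.74	0.76
Ile	free	0.04	0.05
Leu	free	0.08	0.10
Lys	free	0.92	0.76
Met	free	1.08	0.04
Phe	free	0.03	0.03
Pro	free	2.76	0.92
Ser	free	0.52	0.25
Thr	free	0.27	0.24
Tyr	free	0.05	0.06
Val	free	0.14	0.25
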