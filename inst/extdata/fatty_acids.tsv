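analyte	glucose	methanol_glycerol
C16:0	1.22	1.43
C16:1	0.75	0.85
C18:0	0.33	0.34
C18:1	4.28	3.30
C18:2	3.26	3.45
C18:3	0.96	1.30
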