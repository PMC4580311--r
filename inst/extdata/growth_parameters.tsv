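condition	quantity	value	sd	units
glucose	q_glucose	1.02	0.03	mmol/gCDW/h
glucose	CER	2.11	0.07	mmol/gCDW/h
glucose	OUR	2.39	0.07	mmol/gCDW/h
glucose	biomass	28.1	0.3	gCDW/L
glucose	Y_XS	0.54	0.01	gCDW/gSubstrate
glucose	protein_content	0.40	NA	g/gCDW
methanol_glycerol	q_glycerol	1.64	0.06	mmol/gCDW/h
methanol_glycerol	q_methanol	0.81	0.04	mmol/gCDW/h
methanol_glycerol	CER	1.86	0.05	mmol/gCDW/h
methanol_glycerol	OUR	3.09	0.08	mmol/gCDW/h
methanol_glycerol	biomass	31.6	0.3	gCDW/L
methanol_glycerol	Y_XS	0.57	0.02	gCDW/gSubstrate
methanol_glycerol	protein_content	0.54	NA	g/gCDW
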