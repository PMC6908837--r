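protein_name	protein_id	plant_host	timepoint	atom_percent	mag_id	completeness	contamination	taxonomy	genome_size_mbp	n_genes
Glyceraldehyde-3-phosphate dehydrogenase	scaff_0000095019_7	Z. mays	T1	24	MAG43	21	3.6	Unclassified	0.7	692
Glyceraldehyde-3-phosphate dehydrogenase	scaff_0000095019_7	Z. mays	T2	15	MAG43	21	3.6	Unclassified	0.7	692
Glyceraldehyde-3-phosphate dehydrogenase	scaff_0000095019_7	T. aestivum	T2	30	MAG43	21	3.6	Unclassified	0.7	692
Cold shock protein CapA	scaff_0000016092_2	Z. mays	T1	18	MAG44	42	1.8	Pseudomonas	5.5	5207
Chaperone DnaK	scaff_0000160764_4	Z. mays	T1	16	MAG44	42	1.8	Pseudomonas	5.5	5207
Protein with unknown function	scaff_0000030713_6	Z. mays	T2	18	MAG45	54	0.3	Oxalobacteraceae	2.9	2853
Colicin I receptor	scaff_0000049197_5	Z. mays	T2	17	MAG45	54	0.3	Oxalobacteraceae	2.9	2853
Enolase	scaff_0000017170_6	T. aestivum	T2	20	MAG46	29	0	Arthrobacter	2.3	2252
Enolase	scaff_0000017170_6	T. aestivum	T2	28	MAG46	29	0	Arthrobacter	2.3	2252
Dihydrolipoyl dehydrogenase	scaff_0000125141_2	T. aestivum	T1	16	MAG46	29	0	Arthrobacter	2.3	2252
Dihydrolipoyl dehydrogenase	scaff_0000125141_2	T. aestivum	T2	26	MAG46	29	0	Arthrobacter	2.3	2252
Dihydrolipoyl dehydrogenase	scaff_0000125141_2	T. aestivum	T2	46	MAG46	29	0	Arthrobacter	2.3	2252
Protein with unknown function	scaff_0000159039_6	T. aestivum	T2	34	MAG46	29	0	Arthrobacter	2.3	2252
Chaperonin GroEL	scaff_0000063839_3	Z. mays	T1	29	MAG46	29	0	Arthrobacter	2.3	2252
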