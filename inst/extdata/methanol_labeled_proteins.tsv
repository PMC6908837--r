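protein_name	protein_id	mag_id	day3_rep1	day3_rep2	day3_rep3	day8_rep1	day8_rep2	day8_rep3	completeness	contamination	taxonomy	genome_size_mbp	n_genes
Threonine-tRNA ligase	scaff_0000000132_40	MAG47	97	98	98	98	97	98	43	4	Actinomycetales	3.4	3359
XoxF-type methanol dehydrogenase	scaff_0000127167_4	MAG48	55	55	59	72	68	59	37	0	Rhizobiales	2.3	2418
XoxF-type methanol dehydrogenase	scaff_0000032941_13	MAG49	95	98	94	NA	NA	96	17	2	Alphaproteobacteria	1.4	1477
SOS ribosomal protein L5	scaff_0000001175_15	MAG50	93	NA	93	NA	NA	NA	48	5	Proteobacteria	3.1	2996
XoxF-type methanol dehydrogenase	scaff_0000138535_1	MAG51	NA	NA	NA	96	95	95	8	0	Proteobacteria	0.3	300
Transaldolase	scaff_0000073426_7	MAG52	NA	NA	NA	95	NA	94	23	3	Unclassified	1.4	1374
Protein with unknown function	scaff_0000002428_1	MAG53	NA	NA	NA	84	NA	84	66	4	Rhizobiales	2.3	2354
Malate dehydrogenase	scaff_0000012663_3	MAG54	NA	NA	NA	NA	58	67	31	3	Bradyrhizobiaceae	1.8	1781
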