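id	sequence	length	abundance	star_abundance	precursor_length	genomic_region
mir01	TGGAGTGGAGTGGAGTGGAGTGG	23	NA	NA	82	intergenic
mir02	CGTCCTAATCCTTGGCCTG	19	3	10	170	intron
mir03	CGGGAGGGGGAGGGAAGGCT	20	141	NA	193	intergenic
mir04	GGAAGGCTGAGTGCTGCATGT	21	1459	NA	252	intron
mir05	CGGCTGGCTGCGCGGGGACTACG	23	317	190	79	intergenic
mir06	CAGAAACTCACGGACCTCGAC	21	27	NA	76	intergenic
mir07	AGTGGATAGCGTGTTGGG	18	10	NA	82	intergenic
mir08	CAACCATGTGGCGTCGGCACA	21	11	NA	114	intergenic
mir09	GCGGCCCTCGAACGGACACCGG	22	10	NA	80	intron
mir10	CGGAGGAGATGTGCCGTTCCG	21	120	NA	144	intergenic
mir11	CATGTAGGTCGCGAACGGGTT	21	8	NA	119	intergenic
mir12	GTCAGTGAGGACGCTGTATCAAGG	24	12	NA	94	intergenic
mir13	GCGTCAGTCGACCGTGGCACATCC	24	7	1	93	intron
mir14	CGAGGTGTCCGAAGATGTATG	21	15	NA	89	intergenic
mir15	GTGGCTAGTATCCGACGCTGTC	22	11	NA	127	intergenic
mir16	AAGAAGGCCGTGGCGCAACTG	21	75	1	92	intergenic
mir17	CGGGGCTGCCGATTCATCGGT	21	54	NA	85	intergenic
mir18	CGTTGATGAGGCCGATCTGGT	21	21	NA	95	intergenic
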