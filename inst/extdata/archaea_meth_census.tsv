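taxon	rank	parent	n_genomes	genes_m6A	genes_m4C	genes_m5C	meth_genomes	meth_genes_m6A	meth_genes_m4C	meth_genes_m5C	motifs_m6A	motifs_m4C	motifs_m5C
Asgard group	phylum	NA	1	10	7	0	NA	NA	NA	NA	NA	NA	NA
Thermoplasmatota	phylum	NA	18	2.556	2.167	0.444	2	6	4.5	0	5	2.5	0
Aciduliprofundum	class	Thermoplasmatota	2	2	1.5	0	NA	NA	NA	NA	NA	NA	NA
Thermoplasmata	class	Thermoplasmatota	16	2.625	2.25	0.5	NA	NA	NA	NA	NA	NA	NA
Methanomethylophilaceae	order	Thermoplasmata	1	1	0	0	NA	NA	NA	NA	NA	NA	NA
Methanomassiliicoccales	order	Thermoplasmata	5	1.4	1	0.6	NA	NA	NA	NA	NA	NA	NA
Thermoplasmatales	order	Thermoplasmata	9	3.778	3.444	0.222	2	6	4.5	0	5	2.5	0
Unclassified Thermoplasmata	order	Thermoplasmata	1	0	0	3	NA	NA	NA	NA	NA	NA	NA
Crenarchaeota	phylum	NA	100	0.83	0.56	1.1	3	0.667	0.667	1	1	0.667	0.667
Acidilobales	order	Crenarchaeota	3	0.333	0	1	1	0	0	1	0	0	1
Cenarchaeales	order	Crenarchaeota	1	13	12	1	NA	NA	NA	NA	NA	NA	NA
Desulfurococcales	order	Crenarchaeota	17	1	0.882	1.118	1	2	1	1	3	1	0
Fervidicoccales	order	Crenarchaeota	1	0	1	1	NA	NA	NA	NA	NA	NA	NA
Sulfolobales	order	Crenarchaeota	59	0.576	0.441	1	1	0	1	1	0	1	1
Thermofilales	order	Crenarchaeota	5	1	0.4	1.4	NA	NA	NA	NA	NA	NA	NA
Thermoproteales	order	Crenarchaeota	14	0.929	0	1.429	NA	NA	NA	NA	NA	NA	NA
DPANN group	phylum	NA	6	1.333	0.5	0.167	1	1	0	0	1	0	0
Micrarchaeota	class	DPANN group	2	2	1	0	NA	NA	NA	NA	NA	NA	NA
Nanohaloarchaeota DPANN	class	DPANN group	1	2	0	1	NA	NA	NA	NA	NA	NA	NA
Nanoarchaeota	class	DPANN group	3	0.667	0.333	0	1	1	0	0	1	0	0
Environmental sample	phylum	NA	1	6	6	0	NA	NA	NA	NA	NA	NA	NA
Euryarchaeota	phylum	NA	362	3.282	1.442	0.594	39	3.538	1.615	0.641	2.538	1.308	0.103
Archaeoglobi	class	Euryarchaeota	8	1.625	0.375	0.375	NA	NA	NA	NA	NA	NA	NA
Methanoliparia	class	Euryarchaeota	1	4	5	0	NA	NA	NA	NA	NA	NA	NA
Methanomada	class	Euryarchaeota	61	3.033	0.574	0.803	5	4	1.2	1.2	3.4	1	0.2
Methanobacteria	order	Methanomada	36	2.806	0.25	0.528	3	3	0.333	1	2.333	0.333	0
Methanococci	order	Methanomada	24	3.417	1.083	1.208	2	5.5	2.5	1.5	5	2	0.5
Methanopyri	order	Methanomada	1	2	0	1	NA	NA	NA	NA	NA	NA	NA
Methanonatronarchaeia	class	Euryarchaeota	1	0	1	1	NA	NA	NA	NA	NA	NA	NA
Halobacteria	class	Euryarchaeota	181	2.856	2.055	0.657	26	3.462	1.769	0.615	2.461	1.269	0.077
Halobacteriales	order	Halobacteria	94	2.777	1.872	0.638	10	3.1	1.2	0.4	1.6	1.1	0.1
Haloferacales	order	Halobacteria	45	3.2	1.556	0.778	10	3.5	1.5	0.9	2.9	1.1	0.1
Natrialbales	order	Halobacteria	42	2.667	3	0.571	6	4	3.167	0.5	3.167	1.833	0
Methanomicrobia	class	Euryarchaeota	65	6.031	1.277	0.338	4	5	2.5	0.25	2.5	3	0.25
Methanocellales	order	Methanomicrobia	3	4.667	2.667	0.667	NA	NA	NA	NA	NA	NA	NA
Methanomicrobiales	order	Methanomicrobia	19	5.316	2.895	0.368	3	6	3	0.333	3	3.333	0.333
Methanosarcinales	order	Methanomicrobia	42	6.548	0.381	0.262	1	2	1	0	1	2	0
Unclassified Methanomicrobia	order	Methanomicrobia	1	2	4	2	NA	NA	NA	NA	NA	NA	NA
Nanohaloarchaeota	class	Euryarchaeota	1	0	1	0	NA	NA	NA	NA	NA	NA	NA
Thermococci	class	Euryarchaeota	44	1.75	0.5	0.477	4	2	0.25	0.5	2	0.25	0
TACK group	phylum	NA	31	2.065	2.129	0.355	4	1.5	1.5	0.5	1.5	1.25	0.25
Geothermarchaeota	class	TACK group	1	2	0	0	NA	NA	NA	NA	NA	NA	NA
Korarchaeota	class	TACK group	1	1	1	0	NA	NA	NA	NA	NA	NA	NA
Nitrososphaerota	class	TACK group	29	2.103	2.241	0.379	4	1.5	1.5	0.5	1.5	1.25	0.25
Nitrosopumilales	order	Nitrososphaerota	14	1.643	1.071	0.357	3	1.667	1	0.667	1.667	1	0.333
Nitrososphaeria	order	Nitrososphaerota	10	2.8	4.1	0.4	1	1	3	0	1	2	0
Nitrososphaerota inc. sed.	order	Nitrososphaerota	5	2	1.8	0.4	NA	NA	NA	NA	NA	NA	NA
TOTAL	total	NA	519	2.707	1.347	0.665	49	3.245	1.633	0.612	2.429	1.286	0.143
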