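taxon	rank	parent	inline_taxon	n_genomes	IM	IR	IS	IIM	IIR	IIG	IIIM	IIIR	IV	M	C	V	Other
Asgard group	phylum	NA	Lokiarchaeota	1	0	0	0	11	0	4	2	0	0	0	0	0	2
Thermoplasmatota	phylum	NA	NA	18	0.611	0.556	0.444	3.389	0.056	0.389	0.778	0.667	0.556	0	0	0.056	1.667
Aciduliprofundum	class	Thermoplasmatota	NA	2	0.5	0.5	0.5	1.5	0	1	0.5	0.5	0	0	0	0	1
Thermoplasmata	class	Thermoplasmatota	NA	16	0.625	0.562	0.438	3.625	0.062	0.312	0.812	0.688	0.625	0	0	0.062	1.75
Methanomethylophilaceae	order	Thermoplasmata	NA	1	1	1	0	0	0	0	0	0	1	0	0	0	2
Methanomassiliicoccales	order	Thermoplasmata	NA	5	0.6	0.6	0.2	2	0.2	0.2	0.2	0.2	1	0	0	0	1.4
Thermoplasmatales	order	Thermoplasmata	NA	9	0.667	0.556	0.667	5	0	0.444	1.333	1.111	0.333	0	0	0.111	1.444
Unclassified Thermoplasmata	order	Thermoplasmata	NA	1	0	0	0	3	0	0	0	0	1	0	0	0	6
Crenarchaeota	phylum	NA	Thermoprotei	100	0.04	0.04	0.04	1.97	0.03	0.44	0.04	0.03	0	0	0	0.05	1.18
Acidilobales	order	Crenarchaeota	NA	3	0	0	0	1.333	0	0	0	0	0	0	0	0	0.667
Cenarchaeales	order	Crenarchaeota	NA	1	0	0	0	22	0	2	2	2	0	0	0	0	3
Desulfurococcales	order	Crenarchaeota	NA	17	0.059	0.059	0.059	2.294	0	0.647	0	0	0	0	0	0.118	0.824
Fervidicoccales	order	Crenarchaeota	NA	1	0	0	0	2	0	0	0	0	0	0	0	0	0
Sulfolobales	order	Crenarchaeota	NA	59	0.051	0.051	0.051	1.542	0	0.39	0.034	0.017	0	0	0	0	1.271
Thermofilales	order	Crenarchaeota	NA	5	0	0	0	2.4	0.4	0.4	0	0	0	0	0	0.2	0.8
Thermoproteales	order	Crenarchaeota	NA	14	0	0	0	1.929	0.071	0.429	0	0	0	0	0	0.143	1.429
DPANN group	phylum	NA	NA	6	0.333	0.167	0.5	1	0.167	0.167	0.5	0.333	0	0	0	0	0.167
Micrarchaeota	class	DPANN group	NA	2	0	0	0.5	1.5	0.5	0	1.5	1	0	0	0	0	0
Nanohaloarchaeota DPANN	class	DPANN group	Nanohalobia	1	1	1	1	1	0	1	0	0	0	0	0	0	1
Nanoarchaeota	class	DPANN group	NA	3	0.333	0	0.333	0.667	0	0	0	0	0	0	0	0	0
Environmental sample	phylum	NA	NA	1	1	1	1	9	0	1	1	1	0	0	0	0	0
Euryarchaeota	phylum	NA	NA	362	1.124	1.033	1.157	2.798	0.113	1.064	0.152	0.130	0.227	0.180	0	0.055	1.174
Archaeoglobi	class	Euryarchaeota	Archaeoglobales	8	1	0.75	0.875	0.875	0	0.25	0.25	0.25	0	0	0	0	1.375
Methanoliparia	class	Euryarchaeota	NA	1	2	2	2	5	0	2	0	0	0	0	0	0	3
Methanomada	class	Euryarchaeota	NA	61	1	0.951	1.344	2.082	0.262	0.77	0.41	0.328	0.279	0.148	0	0.033	1.656
Methanobacteria	order	Methanomada	NA	36	0.944	0.889	1.472	1.444	0.333	0.611	0.361	0.278	0.472	0.222	0	0.056	1.222
Methanococci	order	Methanomada	NA	24	1.125	1.083	1.208	3.083	0.167	0.958	0.5	0.417	0	0.042	0	0	2.375
Methanopyri	order	Methanomada	NA	1	0	0	0	1	0	2	0	0	0	0	0	0	0
Methanonatronarchaeia	class	Euryarchaeota	NA	1	0	0	0	2	0	0	0	0	0	0	0	1	0
Halobacteria	class	Euryarchaeota	NA	181	0.431	0.409	0.420	3.602	0.11	1.354	0.033	0.028	0.066	0.149	0	0.055	0.890
Halobacteriales	order	Halobacteria	NA	94	0.457	0.426	0.415	3.320	0.128	1.362	0.011	0.011	0.053	0.138	0	0.064	0.904
Haloferacales	order	Halobacteria	NA	45	0.444	0.422	0.489	3.533	0.089	1.4	0.067	0.044	0.133	0.089	0	0.067	0.844
Natrialbales	order	Halobacteria	NA	42	0.357	0.357	0.357	4.31	0.095	1.286	0.048	0.048	0.024	0.238	0	0.024	0.905
Methanomicrobia	class	Euryarchaeota	NA	65	3.585	3.215	3.462	2.462	0.015	0.831	0.323	0.292	0.815	0.446	0	0.077	1.138
Methanocellales	order	Methanomicrobia	NA	3	1	1	1	6	0	0.333	0.667	0.333	0	0	0	0	1.333
Methanomicrobiales	order	Methanomicrobia	NA	19	2.105	1.684	1.789	4.579	0.053	1.105	0.368	0.316	0.737	0.421	0	0.053	1.789
Methanosarcinales	order	Methanomicrobia	NA	42	4.524	4.143	4.476	1.143	0	0.738	0.286	0.286	0.905	0.5	0	0.095	0.833
Unclassified Methanomicrobia	order	Methanomicrobia	NA	1	0	0	0	7	0	1	0	0	1	0	0	0	1
Nanohaloarchaeota	class	Euryarchaeota	NA	1	0	0	0	1	0	0	0	0	0	0	0	0	0
Thermococci	class	Euryarchaeota	Thermococcales	44	0.568	0.568	0.614	1.341	0.091	0.795	0.023	0.023	0	0	0	0.045	1.705
TACK group	phylum	NA	NA	31	0.419	0.419	0.581	3.71	0	0.29	0.129	0	0	0	0	0.097	0.516
Geothermarchaeota	class	TACK group	NA	1	0	0	0	0	0	1	1	0	0	0	0	0	1
Korarchaeota	class	TACK group	NA	1	0	0	0	1	0	1	0	0	0	0	0	0	0
Nitrososphaerota	class	TACK group	NA	29	0.448	0.448	0.621	3.931	0	0.241	0.103	0	0	0	0	0.103	0.517
Nitrosopumilales	order	Nitrososphaerota	NA	14	0.286	0.286	0.571	2.786	0	0	0	0	0	0	0	0	0.714
Nitrososphaeria	order	Nitrososphaerota	NA	10	0.6	0.6	0.6	5.8	0	0.7	0.2	0	0	0	0	0.3	0.1
Nitrososphaerota inc. sed.	order	Nitrososphaerota	NA	5	0.6	0.6	0.8	3.4	0	0	0.2	0	0	0	0	0	0.8
TOTAL	total	NA	NA	519	0.844	0.776	0.873	2.721	0.089	0.869	0.160	0.125	0.177	0.125	0	0.056	1.141
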