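taxon	rank	size	family	count	system_class	motif	meth_type
Crenarchaeota	phylum	100	HG2	99	IIM	CCWGG	m5C
Sulfolobus acidocaldarius	species	9	HG15	8	IIM/R	GGCC	m4C
Archaeoglobi	class	8	HG6	6	IM/R	NA	NA
Methanobacterium	genus	12	HG3	10	IIM	GATC	m6A
Methanococci	order	24	HG2	19	IIM	CCWGG	m5C
Methanococcus maripaludis	species	9	HG3	9	IIM	GATC	m6A
Halobacteria	class	182	HG1	155	IIM	CTAG	m4C
Halorubraceae	family	20	HG3	15	IIM	GATC	m6A
Natrialbales	order	42	HG4	41	IIM	CATTC	m6A
Haloterrigena	genus	9	HG5	7	BREX	CTGGAG	m6A
Methanomicrobiales	order	19	HG3	15	IIM	GATC	m6A
Methanoculleus	genus	6	HG16	6	IIM	AGCT	m4C
M-regula/M-spirilla group	family	6	HG16	6	IIM	AGCT	m4C
M-regula/M-spirilla group	family	6	HG18	6	IIM	GTAC	m4C
M-regula/M-spirilla group	family	6	HG20	6	IIM	CTNAG	m4C
Methanosarcinales	order	42	HG8	28	IM/R/S	NA	NA
Methanosarcina	genus	29	HG9	22	IV	NA	NA
Methanosarcina mazei	species	9	HG17	7	IM/R	NA	NA
Methanosarcina mazei	species	9	HG13	7	BREX	NA	NA
Methanosarcina mazei	species	9	HG14	9	IM/R	NA	NA
Methanosarcina mazei	species	9	HG7	9	IM/R/S	NA	NA
Pyrococcus	genus	9	HG2	9	IIM	CCWGG	m5C
Nitrososphaerota	class	29	HG3	27	IIM	GATC	m6A
Nitrosopumilales	order	14	HG11	14	IIM	AGCT	m4C
Nitrososphaerales	order	8	HG10	8	IIM	GTAC	m4C
Nitrososphaerales	order	8	HG19	8	IIM	AGCT	m4C
Nitrososphaera	genus	5	HG12	5	IIM	CGCG	m4C
Nitrososphaera	genus	5	HG21	5	IIM	NA	m4C
Nitrososphaerota inc. sed.	family	5	HG11	4	IIM	AGCT	m4C
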