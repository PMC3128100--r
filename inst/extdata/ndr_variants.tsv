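cell_type	trait	locus	snp_id	maf	annotation	index_snp_id	r2	distance_kb
MK	MPV	FLJ36031-PIK3CG	rs342293	0.45	Intergenic	rs342293	1.00	0
MK	MPV	DNM3	rs2038479	0.16	Intronic	rs10914144	0.94	10
EB	MCV	HBS1L-MYB	rs7775698	0.22	Intergenic	rs9402686	0.85	9
EB/MK	MPV	TMCC2	rs1172147	0.35	Intronic	rs1668873	0.89	10
EB/MK	PLS	PEAR1	rs4661069	0.11	Promoter	rs3737224	0.83	17
EB/MK	PLS	RAF1	rs3806661	0.30	Promoter	rs3729931	0.85	79
EB/MK	SBP	CYP17A1-C10orf32	rs3824754	0.07	Intronic	rs1004467	1.00	19
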