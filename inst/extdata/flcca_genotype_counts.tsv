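snp_id	gene	chrom	pos	effect_allele	other_allele	case_ref	case_het	case_hom	ctrl_ref	ctrl_het	ctrl_hom	adj_additive_or	adj_additive_p
rs2646260	COL6A3	chr2	238277795	G	A	1802	1366	285	1829	1527	354	0.91	0.008
rs7683000	BST1	chr4	15647074	G	A	2027	1224	202	2264	1252	194	1.08	0.040
rs73224660	BST1	chr4	15714762	A	G	2067	1210	176	2330	1208	172	1.10	0.014
rs7674623	ANTXR2	chr4	80794681	T	C	3131	311	11	3411	293	6	1.18	0.037
rs7671511	SPARCL1	chr4	88449181	T	C	1723	1405	325	1897	1525	288	1.07	0.049
rs2776937	NRP1	chr10	33606189	A	G	1213	1670	570	1361	1794	555	1.07	0.049
rs62069916	APOH	chr17	64280503	T	C	1224	1642	587	1268	1736	706	0.94	0.047
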