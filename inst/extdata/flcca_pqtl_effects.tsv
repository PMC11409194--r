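snp_id	protein_id	gene	beta_sign	p_value	role
rs2646260	COL6A3	COL6A3	-1	7.41e-62	suppressor
rs7683000	BST1	BST1	-1	4.90e-86	suppressor
rs73224660	BST1	BST1	-1	1e-300	suppressor
rs7674623	ANTXR2	ANTXR2	1	1.32e-100	suppressor
rs7671511	SPARCL1	SPARCL1	1	1e-300	suppressor
rs2776937	NRP1	NRP1	-1	2.09e-22	suppressor
rs62069916	APOH	APOH	1	3.98e-10	suppressor
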