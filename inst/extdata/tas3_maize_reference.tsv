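locus	gene_id	tasirnas_per_strand	n_tasirarfs	phasing_score	reads_wt	fold_wt_mut
tas3a	GRMZM2G178686	13	2	63.70	408	52.9
tas3b	GRMZM2G020468	10	2	41.46	1894	28.15
tas3c	GRMZM2G084821	10	2	30.54	854	84.58
tas3d	GRMZM2G124744	12	1	42.81	6382	110.92
tas3e	GRMZM5G806469	9	1	50.08	3475	251.64
tas3f	GRMZM2G155490	14	1	11.80	22	23.2
tas3g	GRMZM2G082055	10	1	50.57	18325	40.71
tas3h	GRMZM2G588623	10	0	4.97	16	19.25
tas3i	GRMZM2G512113	9	1	45.31	8013	28.59
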