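entrez_id	gene_symbol	qj_mean_expression	qj_fold_change	qj_p_value	wyh_mean_expression	wyh_fold_change	wyh_p_value
16000	Igf1	64.23	0.490	0.013	77.62	0.595	0.057
108097	Prkab2	467.22	0.457	0.040	515.14	0.459	0.045
21809	Tgfb3	468.04	0.237	0.021	658.34	0.327	0.078
21813	Tgfbr2	569.39	0.621	0.515	351.72	0.467	0.013
21808	Tgfb2	71.23	0.128	0.012	93.69	0.166	0.019
18115	Nnt	45948.78	2.120	0.001	37695.71	1.660	0.008
23959	Nt5e	263.38	1.640	0.030	313.56	2.040	0.011
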