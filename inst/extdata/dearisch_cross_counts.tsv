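cross_type	genotype	hearing_class	n	n_male	n_female
het_x_het	wt	unaffected	37	23	15
het_x_het	wt	intermediate	2	1	1
het_x_het	wt	affected	0	0	0
het_x_het	het	unaffected	32	25	7
het_x_het	het	intermediate	21	13	8
het_x_het	het	affected	19	13	6
het_x_het	hom	unaffected	0	0	0
het_x_het	hom	intermediate	0	0	0
het_x_het	hom	affected	0	0	0
het_x_wt	wt	unaffected	35	19	16
het_x_wt	wt	intermediate	1	1	0
het_x_wt	wt	affected	0	0	0
het_x_wt	het	unaffected	27	15	12
het_x_wt	het	intermediate	13	8	5
het_x_wt	het	affected	9	6	3
het_x_wt	hom	unaffected	0	0	0
het_x_wt	hom	intermediate	0	0	0
het_x_wt	hom	affected	0	0	0
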