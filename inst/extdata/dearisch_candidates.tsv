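gene	chrom	pos	ref	alt	genotype	consensus_quality	snp_quality	mapping_quality	read_depth	category	detail	background_call	mutant_call
1700001K19Rik	12	111907080	T	A	hom_alt	20	51	58	63	nonsynonymous	H:L	Deletion	Deletion
1700104B16Rik	8	34841236	G	C	het	76	76	55	54	nonsynonymous	H:D	G/C	G/C
Acsl3	1	78692680	C	A	hom_alt	7	25	49	16	stop_gained		C	C
Bcl2l14	6	134377474	T	G	hom_alt	3	36	50	64	nonsynonymous	N:K	NA	Deletion
Btnl7	17	34670007	C	T	het	6	96	48	30	nonsynonymous	G:R	C/T	C/T
Catsper2	2	121223476	T	C	hom_alt	33	33	47	83	nonsynonymous	N:D	Deletion	Deletion
Col6a3	1	92672331	C	G	hom_alt	30	30	60	16	essential_splice_site		NA	Deletion
Creb3l2	6	37284584	T	C	het	38	38	54	23	essential_splice_site		T	T
Gm10859	2	5833494	A	G	het	41	48	56	18	nonsynonymous	I:V	Deletion	Deletion
Gm11149	9	49380322	A	C	hom_alt	0	36	54	30	nonsynonymous	Q:P	Deletion	Deletion
Gtf3c2	5	31476808	T	C	het	25	25	49	39	nonsynonymous	E:G	T	T
H2-Oa	17	34229420	T	C	het	3	35	48	86	nonsynonymous	V:A	Deletion	Deletion
Ido1	8	25703857	C	T	het	21	21	50	30	nonsynonymous	R:K	C	C
Isl1	13	117098488	T	C	het	199	228	60	66	nonsynonymous	Y:C	T	C/T
Mdc1	17	35984844	G	T	hom_alt	13	39	50	11	nonsynonymous	E:D	G	G
Olfr424	1	176066876	A	G	het	4	58	58	88	essential_splice_site		Insertion	A
Olfr573-ps1	7	110091057	G	T	hom_alt	21	25	56	82	nonsynonymous	H:Q	Deletion	Deletion
Olfr573-ps1	7	110091058	T	A	hom_alt	22	45	53	79	nonsynonymous	H:L	Deletion	Deletion
Olfr749	14	51356853	G	T	het	36	36	46	81	nonsynonymous	Q:K	Deletion	Deletion
Rsf1	7	104809403	G	C	het	17	22	54	47	nonsynonymous	E:Q	Deletion	Deletion
Rsf1	7	104809404	A	T	het	14	22	54	47	nonsynonymous	E:V	Deletion	Deletion
Sap30bp	11	115825338	G	A	het	31	31	55	61	nonsynonymous	A:T	G	G
U1	1	172958261	T	A	het	18	105	51	69	essential_splice_site		Deletion	Deletion
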