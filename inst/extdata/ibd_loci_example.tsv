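locus_id	tag_snp	chrom	gene_name	gene_start	gene_end
locus_RPS6KA2	rs11758967	6	RPS6KA2	167161726	167161726
locus_HLA-DQB1	rs1130368	6	HLA-DQB1	32632818	32632818
locus_CARD9	rs28545822	9	CARD9	139217805	139217805
locus_SMAD3	rs36221701	15	SMAD3	67357990	67487569
locus_NOS2	rs12709500	17	NOS2	26134974	26134974
locus_HNF4A	rs6031593	20	HNF4A	43051213	43051213
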