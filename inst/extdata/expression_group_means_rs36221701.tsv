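gene_name	chrom	gene_start	gene_end	fpkm_0	fpkm_1	fpkm_2
SMAD6	15	66994673	67074338	0.02	0	0
SMAD3	15	67357990	67487569	43.91	76.33	120.47
IQCH	15	67547137	67819641	0.10	0.07	0
C15orf61	15	67547137	67819641	17.97	20.62	18.43
MAP2K5	15	67835020	68099455	10.44	8.42	6.71
SKOR1	15	68112041	68126174	0.02	0.01	0
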