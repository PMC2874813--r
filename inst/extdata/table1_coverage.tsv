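chromosome	pseudomolecule_bp	aligned_bp	n_reads	read_bp	n_contigs	n_snps
1	45064769	36886997	21887208	719138056	63889	10980
2	36823111	31152504	19972645	656243813	53822	4113
3	37257345	32175988	19309856	634463329	51236	2773
4	35863200	27331878	15718358	516454041	69662	9891
5	30039014	24458877	14277427	469092491	51892	1032
6	32124789	25763900	14992102	492566411	53317	1165
7	30357780	24230102	13935933	457866127	55090	7561
8	28530027	22970652	13106335	430601662	53667	6426
9	23843360	19060074	11008304	361678832	41137	178
10	23661561	18592212	10572960	347371203	43569	3617
11	30828668	22439806	12582930	413402408	58282	12216
12	27757321	21114982	11932390	392027726	58990	7099
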