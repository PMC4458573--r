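row_id	annotation	region	start	end	hit_pattern	rpkm_rh	rpkm_nrh	log2fc_printed
AT1G18460	Alpha/beta-hydrolases superfamily protein	promoter	2170	2154	AACGTGAACACCATGGA	142.28	60.44	-1.24
AT1G18470	Transmembrane fragile-X-F-associated protein	promoter	831	815	AACGTGAAACACATGTT	104.71	48.45	-1.11
AT2G31350	GLX2-5, glyoxalase 2-5	promoter	1950	1966	ACTATGTGGATCACGTT	163.77	15.16	-3.43
AT2G33320	Calcium-dependent lipid-binding (CaLB domain) family protein	promoter	2495	2479	AACGTGAAAAACATAGA	9.96	3.39	-1.56
AT3G45530	Cysteine/Histidine-rich C1 domain family protein	promoter	344	328	AACGTGAAAACCAAAAA	3.22	0.09	-5.1
AT2G31350.1-1	GLX2-5, glyoxalase 2-5	intron	161	145	TACGTGATGATCATTTT	163.77	15.16	-3.43
AT3G19050.1-19	POK2, phragmoplast orienting kinesin 2	intron	25	41	TTCTTGTGCATCACGTA	0.47	4.6	3.29
AT4G03500.1-1	Ankyrin repeat family protein	intron	856	840	TACGTGCTAAGCAAATT	16.3	2.45	-2.73
AT5G27680.1-8	RECQSIM, RECQ helicase SIM	intron	72	56	TACGTGCTATTCAAATT	0.18	2.15	3.59
AT1G18460.1	Alpha/beta-Hydrolases superfamily protein	cds	1435	1451	AACATGTGTTTCACGTT	142.28	60.44	-1.24
AT1G18470.1	Transmembrane Fragile-X-F-associated protein	cds	466	482	TCCATGGTGTTCACGTT	104.71	48.45	-1.11
AT2G33320.1	Calcium-dependent lipid-binding (CaLB domain) family protein	cds	254	270	TCCGTGATGTTCACGTT	9.96	3.39	-1.56
AT3G19050.1	POK2, phragmoplastorienting kinesin 2	cds	2555	2571	ATTTTGAGCCGCACGAA	0.47	4.6	3.29
AT3G45530.1	Cysteine/Histidine-rich C1 domain family protein	cds	1442	1458	TCCATGGAAGTCACGAT	3.22	0.09	-5.1
AT4G03500.1	Ankyrin repeat family protein	cds	1723	1739	TTTATGGCTGGCACGTA	16.3	2.45	-2.73
AT5G27680.1	RECQSIM, RECQ helicase SIM	cds	1241	1257	ATTTTGGTTCTCACGAT	0.18	2.15	3.59
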