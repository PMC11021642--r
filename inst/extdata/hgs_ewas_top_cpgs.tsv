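# Published epigenome-wide association results for handgrip strength in
# discordant MZ twin pairs: the 25 CpGs reaching FDR < 0.05 (GEE coefficient
# is M-value change per kg of handgrip strength).
chrom	pos	coefficient	p	fdr	ensembl_gene_id	symbol
chr22	45948613	0.042	7.63e-13	7.18e-08	ENSG00000077942	FBLN1
chr22	45948616	0.042	8.02e-13	7.18e-08	ENSG00000077942	FBLN1
chr22	45948620	0.042	8.74e-13	7.18e-08	ENSG00000077942	FBLN1
chr22	45948590	0.041	7.16e-12	4.41e-07	ENSG00000077942	FBLN1
chr22	45948556	0.039	2.98e-09	1.47e-04	ENSG00000077942	FBLN1
chr9	137240415	-0.035	3.27e-08	1.17e-03	ENSG00000186350	RXRA
chr9	137240420	-0.035	3.31e-08	1.17e-03	ENSG00000186350	RXRA
chr22	45948659	0.048	4.33e-08	1.33e-03	ENSG00000077942	FBLN1
chr3	52007647	0.311	5.84e-08	1.60e-03	ENSG00000114779	ABHD14B
chr9	137240405	-0.034	1.07e-07	2.63e-03	ENSG00000186350	RXRA
chr3	52007565	0.284	2.29e-07	5.14e-03	ENSG00000114779	ABHD14B
chr9	137240398	-0.034	3.09e-07	5.85e-03	ENSG00000186350	RXRA
chr22	45948675	0.059	3.09e-07	5.85e-03	ENSG00000077942	FBLN1
chr14	53131877	-0.269	3.83e-07	6.75e-03	ENSG00000197930	ERO1L
chr3	52007520	0.269	5.21e-07	8.56e-03	ENSG00000114779	ABHD14B
chr9	140117008	0.223	8.26e-07	1.27e-02	NA	NA
chr2	191295760	0.250	1.40e-06	2.03e-02	ENSG00000151690	MFSD6
chr22	45948525	0.035	1.67e-06	2.14e-02	ENSG00000077942	FBLN1
chr15	91369952	-0.163	1.72e-06	2.14e-02	NA	NA
chr12	120032854	0.020	1.74e-06	2.14e-02	ENSG00000224982	TMEM233
chr7	72285112	-0.222	3.70e-06	4.35e-02	ENSG00000254184	TYW1B
chr3	52007573	0.244	4.32e-06	4.84e-02	ENSG00000114779	ABHD14B
chr2	114035021	0.036	4.64e-06	4.85e-02	ENSG00000125618	PAX8
chr7	72285120	-0.221	4.88e-06	4.85e-02	ENSG00000254184	TYW1B
chr11	1993029	-0.123	4.92e-06	4.85e-02	ENSG00000214026	MRPL23
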