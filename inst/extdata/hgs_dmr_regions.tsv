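# Published differentially methylated regions for handgrip strength
# (Stouffer-Liptak-Kechris corrected p < 0.05).  n_cpgs is the member CpG
# count of each region; coordinates are 1-based inclusive.
dmr_id	chrom	start	end	n_cpgs	slk_p	symbol	location
A	chr22	45948412	45948733	13	8.08e-14	FBLN1	At
B	chr4	778877	779232	31	1.11e-03	CPLX1	At
C	chr20	23636303	23636792	20	1.17e-03	CST3	Near
D	chr8	145011455	145011859	17	1.20e-03	PLEC	At
E	chr8	117962019	117962182	18	1.34e-03	SLC30A8	Near
F	chr17	76354791	76355185	28	1.39e-03	SOCS3	At
G	chr21	45232096	45232383	15	7.28e-03	AATBC	At
H	chr1	38456158	38456303	10	8.03e-03	SF3A3	Near
I	chr17	76880072	76880441	16	9.52e-03	TIMP2	At
J	chr6	108497677	108497832	17	9.96e-03	NR2E1	At
K	chr11	1780075	1780482	17	1.40e-02	CTSD	At
L	chr7	149389727	149389874	16	1.73e-02	KRBA1	Near
M	chr10	131770987	131771418	36	1.90e-02	EBF3	Near
N	chr19	4542957	4543889	52	2.14e-02	SEMA6B	At
O	chr16	30615708	30616651	31	2.25e-02	ZNF689	At
P	chr19	852547	853044	25	2.46e-02	ELANE	At
Q	chr7	137831775	137832090	16	2.69e-02	AKR1D1	Near
R	chr9	95947588	95947708	16	2.93e-02	WNK2	At
S	chr15	37402530	37402656	11	2.98e-02	WDR70	At
T	chr13	58204218	58204367	14	3.37e-02	PCDH17	Near
U	chr16	3493343	3493506	16	4.84e-02	ZNF597	At
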