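# 18-SNP type 2 diabetes panel, Rotterdam study replication.
# Identical to the GoDARTS panel except for the three SNPs whose cited GWAS
# differs between the two prediction studies (KCNJ11, TCF2, TCF7L2).
# raf: approximate risk-allele control frequencies for European-ancestry
# populations, compiled from the GWAS literature; synthetic stand-ins for
# the exact frequencies used in the original replication.
snp_id	gene	raf	or_allele	ci_low	ci_high
rs2641348	ADAM30/NOTCH2	0.10	1.10	1.06	1.15
rs4607103	ADAMTS9	0.76	1.09	1.06	1.12
rs12779790	CDC123	0.18	1.11	1.07	1.14
rs10946398	CDKAL1	0.32	1.12	1.08	1.16
rs10811661	CDKN2A/2B	0.85	1.20	1.14	1.25
rs564398	CDKN2A/2B	0.58	1.12	1.07	1.17
rs8050136	FTO	0.40	1.15	1.09	1.22
rs1111875	HHEX-IDE	0.56	1.13	1.08	1.17
rs4402960	IGF2BP2	0.30	1.17	1.10	1.25
rs864745	JAZF1	0.50	1.10	1.07	1.13
rs5219	KCNJ11	0.46	1.14	1.10	1.19
rs1801282	PPARG	0.85	1.14	1.08	1.20
rs13266634	SLC30A8	0.75	1.12	1.07	1.16
rs757210	TCF2	0.43	1.22	1.15	1.30
rs7903146	TCF7L2	0.30	1.38	1.31	1.46
rs7578597	THADA	0.90	1.15	1.10	1.20
rs7961581	TSPAN8/LGR5	0.27	1.09	1.06	1.12
rs10010131	WFS1	0.60	1.11	1.07	1.16
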