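# Published genetic risk prediction studies and the AUC obtained for each by
# the repeated-simulation replication (GWAS odds ratios and frequencies,
# 100 iterations of 100,000 individuals). published_auc is the value the
# prediction study reported; simulated_auc is the replication estimate.
study_id	disease	design	sample_size	n_snps	model_type	published_auc	simulated_auc
peter_2009	Crohn disease	case-control	872	7	unweighted	0.70	0.67
johansson_2012	prostate cancer	case-control	1508	33	unweighted	0.64	0.67
yamashita_2011	type 1 diabetes	case-control	1743	7	unweighted	0.65	0.64
lin_2009	type 2 diabetes	cross-sectional	5360	15	unweighted	0.57	0.59
qi_2011	type 2 diabetes	prospective cohort	3210	17	unweighted	0.62	0.60
van_hoek_2008	type 2 diabetes	prospective cohort	6544	18	unweighted	0.56	0.60
meigs_2008	type 2 diabetes	prospective cohort	2377	18	unweighted	0.58	0.59
wang_2010	type 2 diabetes	cross-sectional	7232	19	unweighted	0.55	0.60
talmud_2010	type 2 diabetes	prospective cohort	5535	20	unweighted	0.54	0.60
sun_2011	prostate cancer	case-control	4621	28	weighted	0.62	0.66
kader_2012	prostate cancer	case-control	1654	33	weighted	0.59	0.67
lin_2009_w	type 2 diabetes	cross-sectional	5360	15	weighted	0.59	0.60
talmud_2010_w	type 2 diabetes	prospective cohort	5535	20	weighted	0.55	0.61
scholl_2007	age-related macular degeneration	case-control	179	3	logistic	0.73	0.69
hecker_2010	age-related macular degeneration	case-control	274	4	logistic	0.77	0.76
grassmann_2012	age-related macular degeneration	case-control	1782	13	logistic	0.82	0.78
dunlop_2012	colorectal cancer	case-control	39266	10	logistic	0.57	0.60
lubbe_2012	colorectal cancer	prospective cohort	14929	14	logistic	0.58	0.60
peter_2009_lr	Crohn disease	case-control	872	7	logistic	0.71	0.68
aly_2011	prostate cancer	prospective cohort	5241	36	logistic	0.67	0.69
helfand_2011	prostate cancer	case-control	1464	9	logistic	0.61	0.62
weedon_2006	type 2 diabetes	case-control	6077	3	logistic	0.58	0.59
vaxillaire_2008	type 2 diabetes	prospective cohort	5212	3	logistic	0.56	0.58
hu_2009	type 2 diabetes	case-control	3634	11	logistic	0.62	0.61
miyake_2009	type 2 diabetes	case-control	2000	11	logistic	0.63	0.63
fontaine_bisson_2010	type 2 diabetes	cross-sectional	2751	17	logistic	0.59	0.61
van_hoek_2008_lr	type 2 diabetes	prospective cohort	6544	18	logistic	0.60	0.61
lango_2008	type 2 diabetes	case-control	4907	18	logistic	0.60	0.61
sparso_2009	type 2 diabetes	case-control	9395	19	logistic	0.60	0.61
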