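# Study configuration for the GoDARTS type 2 diabetes replication.
study_id: t2d_godarts
disease: type 2 diabetes
panel: t2d_godarts.tsv
d: 0.20
model_type: bayes
n_sim: 100000
n_iter: 100
published_auc: 0.60
published_n: 4907
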