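# Population-average disease risks used as the Bayes prior d.
disease	d
type 2 diabetes	0.20
prostate cancer	0.15
type 1 diabetes	0.002
age-related macular degeneration	0.065
colorectal cancer	0.048
Crohn disease	0.002
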