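"step","n_remaining"
"coverage",418
"low_variance",397
"hypo_methylation",322
"hyper_methylation",254
"cg_snp",237
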