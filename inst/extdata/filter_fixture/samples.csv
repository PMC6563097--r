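"sample_id","group","timepoint","tissue","family_id"
"s1","stream","age1","liver","F01"
"s2","stream","age1","liver","F01"
"s3","stream","age1","liver","F01"
"s4","stream","age1","liver","F01"
"s5","hatchery","age1","liver","F01"
"s6","hatchery","age1","liver","F01"
"s7","hatchery","age1","liver","F01"
"s8","hatchery","age1","liver","F01"
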