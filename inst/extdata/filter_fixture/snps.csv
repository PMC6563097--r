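"chrom","pos"
"chrB",37947
"chrA",110226
"chrA",100643
"chrB",176797
"chrB",85416
"chrA",8720
"chrB",76075
"chrB",2521
"chrB",175477
"chrA",29735
"chrA",133855
"chrB",103811
"chrA",22601
"chrA",139846
"chrA",70762
"chrA",74674
"chrB",84657
"chrA",109995
"chrB",68199
"chrA",64197
"chrB",44588
"chrA",33224
"chrB",179300
"chrB",135401
"chrA",90149
"chrB",8558
"chrB",145574
"chrA",129167
"chrB",55495
"chrA",12367
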