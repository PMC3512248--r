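clade	min_age	max_age
root	2.7	3.8
Euryarchaeota	2.7	NA
Thermoplasmatales	NA	2.32
Sulfolobales	NA	2.32
Halobacteriales	NA	2.32
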