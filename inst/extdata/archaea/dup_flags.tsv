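gene	clade	family	flagged
SoxB	sulf	sulfolobales_coxB	0
DoxB	sulf	sulfolobales_coxB	1
FoxA	sulf	sulfolobales_coxB	1
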