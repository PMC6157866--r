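peptide	allele	affinity_nm	tap_score	processing_score	tcr_binding
QATEAERSS	B*35:01	14485.65	-1.01	0.95	Positive
QATEAERSS	C*03:03	28178.94	-1.01	0.95	Positive
QATEAERSF	B*35:01	151.47	1.07	1.3	Positive
QATEAERSF	C*03:03	621.64	1.07	1.3	Positive
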