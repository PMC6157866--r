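donor_id	locus	allele1	allele2
IV.9	A	A*11:01:01:01	A*24:17
IV.9	B	B*15:01:01:01	B*35:01:01:02
IV.9	C	C*03:03:01:01	C*04:01:01:01
IV.2	A	A*01:01:01:01	A*01:01:01:01
IV.2	B	B*35:01:01:02	B*57:01:01
IV.2	C	C*04:01:01:01	C*06:02:01:01
III.5	A	A*01:01:01:01	A*24:17
III.5	B	B*15:01:01:01	B*57:01:01
III.5	C	C*03:03:01:01	C*06:02:01:01
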