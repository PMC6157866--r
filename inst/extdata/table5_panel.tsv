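mut_id	variant	allele	wt_peptide	mut_peptide	n_db_crc	n_db_other
Mut1	p.P2018fsX26	A*11:01	LSSLSIDSE	SVLLVLTLK	2	2
Mut2	p.Q1193fsX14	B*35:01	IPSSQKQSF	IPSSQKVIF	7	2
Mut3	p.K1250fsX5	B*35:01	KAATCKVSS	KAATCSFFY	4	1
Mut3	p.K1250fsX5	A*11:01	KAATCKVSS	KAATCSFFY	4	1
Mut4	p.G1339fsX76	B*08:01	TPKSPPEHY	HPKVHLNTM	5	9
Mut5	p.Q541fsX19	A*24:02	VIASVLRNL	GYCECFEEF	8	1
Mut5	p.Q541fsX19	A*24:17	VIASVLRNL	GYCECFEEF	8	1
Mut6	p.V609fsX25	B*35:01	SQTNTLAII	EPDKHFSHY	2	1
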