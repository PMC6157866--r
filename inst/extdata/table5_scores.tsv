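peptide	allele	affinity_nm	tap_score	processing_score	tcr_binding
LSSLSIDSE	A*11:01	24614.3	NA	NA	NA
SVLLVLTLK	A*11:01	13.71	NA	NA	High
IPSSQKQSF	B*35:01	100.41	NA	NA	NA
IPSSQKVIF	B*35:01	39.17	NA	NA	High
KAATCKVSS	B*35:01	23571.74	NA	NA	NA
KAATCSFFY	B*35:01	41.35	NA	NA	High
KAATCKVSS	A*11:01	20589.91	NA	NA	NA
KAATCSFFY	A*11:01	52.46	NA	NA	High
TPKSPPEHY	B*08:01	23828.16	NA	NA	NA
HPKVHLNTM	B*08:01	52.46	NA	NA	High
VIASVLRNL	A*24:02	13575.13	NA	NA	NA
GYCECFEEF	A*24:02	59.09	NA	NA	High
VIASVLRNL	A*24:17	18866.1	NA	NA	NA
GYCECFEEF	A*24:17	69.17	NA	NA	High
SQTNTLAII	B*35:01	25017.04	NA	NA	NA
EPDKHFSHY	B*35:01	77.03	NA	NA	High
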