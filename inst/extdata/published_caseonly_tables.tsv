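table	assay	row	n_epitope_neg	n_epitope_pos	p_printed	mi_affected
3a	qPCR	3DS1-/3DL1+	183	269	0.4094	FALSE
3a	qPCR	3DS1+/3DL1-	12	21	0.4094	FALSE
3a	qPCR	3DS1+/3DL1+	113	138	0.4094	FALSE
3a	SNP	3DS1-/3DL1+	739	1063	0.4235	FALSE
3a	SNP	3DS1+/3DL1-	40	71	0.4235	FALSE
3a	SNP	3DS1+/3DL1+	396	613	0.4235	FALSE
3b	qPCR	3DL1-	12	21	0.5144	FALSE
3b	qPCR	3DL1+	296	407	0.5144	FALSE
3b	SNP	3DL1-	40	71	0.3609	FALSE
3b	SNP	3DL1+	1135	1676	0.3609	FALSE
3c	qPCR	3DS1-	293	159	0.4922	TRUE
3c	qPCR	3DS1+	159	107	0.4922	TRUE
3c	SNP	3DS1-	1153	649	0.0353	FALSE
3c	SNP	3DS1+	673	447	0.0353	FALSE
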