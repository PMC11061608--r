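sample	source_cohort	histology	reference_class	ne_score
H1341	CCLE	SCLC-Y	Small cell neuroendocrine carcinoma of the cervix	0.2294
DMS114	CCLE	SCLC-Y	SMARCA4-UT	0.1365
SBC5	CCLE	SCLC-Y	SMARCA4-UT	-0.2384
H841	CCLE	SCLC-Y	SMARCA4-UT	-0.3397
H2286	CCLE	SCLC-Y	Adenocarcinoma	-0.6746
H157DM	CCLE	SCLC-Y	Squamous cell carcinoma	-0.7356
H196	CCLE	SCLC-Y	Sarcomatoid malignancy	-0.7438
SW1271	CCLE	SCLC-Y	SMARCA4-deficient malignancy	-0.8004
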