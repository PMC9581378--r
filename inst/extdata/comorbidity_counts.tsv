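variable	group	count
type_2_diabetes	NAS0-1	4
type_2_diabetes	NAS2-3	3
type_2_diabetes	NAS4-6	3
hypertension	NAS0-1	3
hypertension	NAS2-3	5
hypertension	NAS4-6	4
dyslipidemia	NAS0-1	5
dyslipidemia	NAS2-3	2
dyslipidemia	NAS4-6	5
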