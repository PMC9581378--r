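variable	grade	group	count
steatosis	0	NAS0-1	3
steatosis	1	NAS0-1	5
steatosis	2	NAS0-1	0
steatosis	3	NAS0-1	0
steatosis	0	NAS2-3	0
steatosis	1	NAS2-3	6
steatosis	2	NAS2-3	5
steatosis	3	NAS2-3	1
steatosis	0	NAS4-6	0
steatosis	1	NAS4-6	0
steatosis	2	NAS4-6	3
steatosis	3	NAS4-6	3
lobular_inflammation	0	NAS0-1	8
lobular_inflammation	1	NAS0-1	0
lobular_inflammation	2	NAS0-1	0
lobular_inflammation	3	NAS0-1	0
lobular_inflammation	0	NAS2-3	4
lobular_inflammation	1	NAS2-3	8
lobular_inflammation	2	NAS2-3	0
lobular_inflammation	3	NAS2-3	0
lobular_inflammation	0	NAS4-6	0
lobular_inflammation	1	NAS4-6	6
lobular_inflammation	2	NAS4-6	0
lobular_inflammation	3	NAS4-6	0
ballooning	0	NAS0-1	8
ballooning	1	NAS0-1	0
ballooning	2	NAS0-1	0
ballooning	0	NAS2-3	9
ballooning	1	NAS2-3	3
ballooning	2	NAS2-3	0
ballooning	0	NAS4-6	0
ballooning	1	NAS4-6	5
ballooning	2	NAS4-6	1
nas_total	0	NAS0-1	3
nas_total	1	NAS0-1	5
nas_total	2	NAS0-1	0
nas_total	3	NAS0-1	0
nas_total	4	NAS0-1	0
nas_total	5	NAS0-1	0
nas_total	6	NAS0-1	0
nas_total	0	NAS2-3	0
nas_total	1	NAS2-3	0
nas_total	2	NAS2-3	6
nas_total	3	NAS2-3	6
nas_total	4	NAS2-3	0
nas_total	5	NAS2-3	0
nas_total	6	NAS2-3	0
nas_total	0	NAS4-6	0
nas_total	1	NAS4-6	0
nas_total	2	NAS4-6	0
nas_total	3	NAS4-6	0
nas_total	4	NAS4-6	3
nas_total	5	NAS4-6	2
nas_total	6	NAS4-6	1
fibrosis_stage	0	NAS0-1	8
fibrosis_stage	1	NAS0-1	0
fibrosis_stage	2	NAS0-1	0
fibrosis_stage	3	NAS0-1	0
fibrosis_stage	4	NAS0-1	0
fibrosis_stage	0	NAS2-3	9
fibrosis_stage	1	NAS2-3	3
fibrosis_stage	2	NAS2-3	0
fibrosis_stage	3	NAS2-3	0
fibrosis_stage	4	NAS2-3	0
fibrosis_stage	0	NAS4-6	1
fibrosis_stage	1	NAS4-6	2
fibrosis_stage	2	NAS4-6	2
fibrosis_stage	3	NAS4-6	1
fibrosis_stage	4	NAS4-6	0
nash	no	NAS0-1	8
nash	yes	NAS0-1	0
nash	no	NAS2-3	12
nash	yes	NAS2-3	0
nash	no	NAS4-6	1
nash	yes	NAS4-6	5
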