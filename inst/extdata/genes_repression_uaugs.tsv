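gene	label	sequence	fold	cell_line
MOR	MOR-uAUG1	GCCCAUGCUCC	1	HEK293
MOR	MOR-uAUG2	GGGGAUGCUAA	2	HEK293
MOR	MOR-uAUG3	AAGGAUGCGCC	3	HEK293
CHOP	CHOP-uAUG1	UAUCAUGUUAA	1	HeLa
CHOP	CHOP-uAUG2	AAAGAUGAGCG	6	HeLa
CHOP	CHOP-uAUG3	GCAGAUGUGCU	2	HeLa
MDM2	MDM2-uAUG1	AAAGAUGGAGC	3	HeLa
MDM2	MDM2-uAUG2	UGGAAUGAUCC	1	HeLa
ADH5	ADH5-uAUG1	GCCCAUGCCUC	4	HeLa
ADH5	ADH5-uAUG2	CCGGAUGUCAG	4	HeLa
KLF13	KLF13-uAUG1	CACAAUGCGCG	1	Jurkat
KLF13	KLF13-uAUG2	CCCCAUGCGCU	2	Jurkat
KLF13	KLF13-uAUG3	GCGGAUGCGCG	2	Jurkat
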