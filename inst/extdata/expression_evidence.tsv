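mirna	cell_line	expressed	source
hsa-miR-146a	HEK293	No	tableT3
hsa-miR-202	HEK293	No	tableT3
hsa-miR-324-5p	HEK293	Yes	ref42
hsa-miR-517b	HEK293	Yes	ref42
hsa-miR-323-5p	HEK293	No	tableT3
hsa-miR-450b-3p	HEK293	No	tableT3
hsa-miR-574-3p	HeLa	Yes	ref41,ref42
hsa-miR-556-3p	HeLa	No	tableT3
hsa-miR-219-2-3p	HeLa	No	tableT3
hsa-miR-363	HeLa	Yes	ref42
hsa-miR-146a	HeLa	No	tableT3
hsa-miR-202	HeLa	No	tableT3
hsa-miR-219-1-3p	HeLa	No	tableT3
hsa-miR-487a	HeLa	No	tableT3
hsa-miR-489	HeLa	No	tableT3
hsa-miR-323-5p	Jurkat	No	tableT3
hsa-miR-103	Jurkat	Yes	ref41
hsa-miR-107	Jurkat	Yes	ref41
hsa-miR-33a	Jurkat	Yes	ref44,ref45
hsa-miR-586	Jurkat	No	tableT3
hsa-miR-202	Jurkat	No	tableT3
hsa-miR-450b-3p	Jurkat	No	tableT3
hsa-miR-324-5p	Jurkat	Yes	ref41,ref44
hsa-miR-583	HeLa	Yes	ref42
hsa-miR-380	HeLa	Yes	ref42
hsa-miR-576-5p	HeLa	Yes	ref42
hsa-miR-16	HeLa	Yes	ref41,ref42
mmu-miR-16	N2A	Yes	ref41,ref43
hsa-miR-31	HeLa	Yes	ref41,ref42
hsa-miR-324-5p	HeLa	Yes	ref41,ref42
hsa-miR-609	HeLa	Yes	ref42
hsa-miR-188-5p	HeLa	Yes	ref42
mmu-miR-487b	N2A	Yes	ref43
hsa-miR-103	HeLa	Yes	ref42
mmu-miR-103	N2A	Yes	ref43
hsa-miR-107	HeLa	Yes	ref42
mmu-miR-107	N2A	Yes	ref43
hsa-miR-338-3p	HeLa	Yes	ref41,ref42
mmu-miR-376b	N2A	Yes	ref43
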