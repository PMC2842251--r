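gene	label	sequence	fold
KLF9	uAUG1	CAUAAUGGGGU	NA
KLF9	uAUG2	AAAGAUGUGUC	NA
KLF9	uAUG3	GCCAAUGCCAG	NA
KLF9	uAUG4	AAAGAUGUGUC	NA
KLF9	uAUG5	UUAAAUGUCAG	NA
KLF9	uAUG6	CGUGAUGGGAU	5
KLF9	uAUG7	GAGAAUGCCGG	2
KLF9	uAUG8	GUGAAUGUCCU	NA
KLF9	uAUG9	GUGGAUGCUGC	NA
KLF9	uAUG10	AAAGAUGAGGG	NA
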