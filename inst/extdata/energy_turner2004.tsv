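# parameter_set_id: turner2004-stack37
# RNA nearest-neighbor stacking free energies at 37 C (kcal/mol),
# Turner 2004 set as distributed with ViennaRNA.  dg37(pair1,pair2) is
# the stack 5'-XY-3'/3'-X'Y'-5' with pair1 = X:X', pair2 = Y:Y'.
# duplex_init is 0.0 by default: reported hybridization energies are on
# the scale used by duplex screening tools, which omit the bimolecular
# initiation term (+4.10 in the Turner set; set it explicitly to add it).
# terminal_au is the per-helix-end penalty for a closing A:U or G:U pair.
term	pair1	pair2	dg37
stack	CG	CG	-3.3
stack	GC	CG	-3.4
stack	GU	CG	-2.5
stack	UG	CG	-1.5
stack	AU	CG	-2.2
stack	UA	CG	-2.4
stack	CG	GC	-2.4
stack	GC	GC	-3.3
stack	GU	GC	-2.1
stack	UG	GC	-1.4
stack	AU	GC	-2.1
stack	UA	GC	-2.1
stack	CG	GU	-1.4
stack	GC	GU	-1.5
stack	GU	GU	-0.5
stack	UG	GU	0.3
stack	AU	GU	-0.6
stack	UA	GU	-1
stack	CG	UG	-2.1
stack	GC	UG	-2.5
stack	GU	UG	1.3
stack	UG	UG	-0.5
stack	AU	UG	-1.4
stack	UA	UG	-1.3
stack	CG	AU	-2.1
stack	GC	AU	-2.4
stack	GU	AU	-1.3
stack	UG	AU	-1
stack	AU	AU	-0.9
stack	UA	AU	-1.3
stack	CG	UA	-2.1
stack	GC	UA	-2.2
stack	GU	UA	-1.4
stack	UG	UA	-0.6
stack	AU	UA	-1.1
stack	UA	UA	-0.9
duplex_init	NA	NA	0
terminal_au	NA	NA	0.5
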