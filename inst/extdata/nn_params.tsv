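# RNA:RNA nearest-neighbor duplex free-energy parameters, kcal/mol at 37 C.
# Watson-Crick stacks per Xia et al. 1998; GU stacks per the Turner rules
# (Mathews et al. 1999 lineage). step is 5'XY3'/3'WZ5' with X:W and Y:Z paired.
type	key	kcal
stack	CC/GG	-3.3
stack	CG/GC	-2.4
stack	CG/GU	-1.4
stack	CU/GG	-2.1
stack	CA/GU	-2.1
stack	CU/GA	-2.1
stack	GC/CG	-3.4
stack	GG/CC	-3.3
stack	GG/CU	-1.5
stack	GU/CG	-2.5
stack	GA/CU	-2.4
stack	GU/CA	-2.2
stack	GC/UG	-2.5
stack	GG/UC	-2.1
stack	GG/UU	-0.5
stack	GU/UG	1.3
stack	GA/UU	-1.3
stack	GU/UA	-1.4
stack	UC/GG	-1.5
stack	UG/GC	-1.4
stack	UG/GU	0.3
stack	UU/GG	-0.5
stack	UA/GU	-1
stack	UU/GA	-0.6
stack	AC/UG	-2.2
stack	AG/UC	-2.1
stack	AG/UU	-0.6
stack	AU/UG	-1.4
stack	AA/UU	-0.9
stack	AU/UA	-1.1
stack	UC/AG	-2.4
stack	UG/AC	-2.1
stack	UG/AU	-1
stack	UU/AG	-1.3
stack	UA/AU	-1.3
stack	UU/AA	-0.9
init	.	4.09
terminal_au	.	0.45
terminal_gu	.	0.45
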