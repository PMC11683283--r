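top5p3p	bottom3p5p	dg37_kcal_mol
AA	UU	-0.93
AU	UA	-1.10
UA	AU	-1.33
CU	GA	-2.08
CA	GU	-2.11
GU	CA	-2.24
GA	CU	-2.35
CG	GC	-2.36
GG	CC	-3.26
GC	CG	-3.42
AG	UU	-0.60
AU	UG	-1.40
UG	AU	-1.00
GA	UU	-1.30
CG	GU	-1.40
CU	GG	-2.10
GG	CU	-1.50
GU	CG	-2.50
GG	UU	-0.50
GU	UG	1.30
UG	GU	0.30
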