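loop_type	size	dg37_kcal_mol
bulge	1	3.80
bulge	2	2.80
bulge	3	3.20
bulge	4	3.60
bulge	5	4.00
bulge	6	4.40
internal	2	1.00
internal	3	1.00
internal	4	1.10
internal	5	2.00
internal	6	2.00
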