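mhc2_mouse	14 mouse MHC class II molecules	Cd74	Ciita	H2-Aa	H2-Ab1	H2-DMa	H2-DMb1	H2-DMb2	H2-Ea-ps	H2-Eb1	H2-Eb2	H2-K1	H2-Oa	H2-Ob	Mr1
cosignal_partial	partial co-signaling receptor panel; incomplete: the full 28-gene panel exists only as a figure	LIGHT	4-1BBL	CD48	B7-1	CD112	Galectin-9	B7-DC	HVEM
housekeeping_human	human housekeeping panel as printed	PRS27A	GADPH	ARHGDIA
housekeeping_mouse	mouse housekeeping panel	Ldha	Nono	Rpl32
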