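printed	canonical	note
GADPH	GAPDH	housekeeping panel spelling as printed
PRS27A	RPS27A	housekeeping panel spelling as printed
CCLL5	CCL15	call-matrix OCR variant
L12RB1	IL12RB1	call-matrix OCR variant
L13	IL13	call-matrix OCR variant
IL7B	IL17B	call-matrix OCR variant
L10RB	IL10RB	call-matrix OCR variant
H2-Abl	H2-Ab1	lowercase-L/one confusion; NCBI Gene ID 14961
Mrl	Mr1	lowercase-L/one confusion; NCBI Gene ID 15064
B7-1	CD80	co-signaling panel synonym
4-1BBL	TNFSF9	co-signaling panel synonym
LIGHT	TNFSF14	co-signaling panel synonym
HVEM	TNFRSF14	co-signaling panel synonym
B7-DC	PDCD1LG2	co-signaling panel synonym
Galectin-9	LGALS9	co-signaling panel synonym
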