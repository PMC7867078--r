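bait	direction	gene_id	mirnas
ERalpha	down	ESR1	miR-181c-5p;miR-185-3p
ERalpha	down	ENAH	miR-181a-5p;miR-181c-5p
ERalpha	down	STRBP	miR-181a-5p
ERalpha	down	TBC1D9	miR-181a-5p;miR-181c-5p;miR-451
ERalpha	down	USP32	let-7f-5p
ERalpha	down	PKP4	miR-193a-3p
ERalpha	down	OSBPL8	miR-181a-5p;miR-181c-5p
ERalpha	down	TBL1XR1	miR-181a-5p;miR-181c-5p;miR-193a-3p
LSD1	down	ANKRD50	miR-181a-5p;miR-181c-5p
LSD1	down	CCDC6	miR-181a-5p;miR-181c-5p
LSD1	down	DCLK1	miR-181a-5p;miR-181c-5p
LSD1	down	TANC2	miR-146a-5p;miR-181a-5p;miR-181c-5
LSD1	down	TBC1D1	miR-181a-5p;miR-181c-5p
LSD1	down	USP32	let-7f-5p
ERalpha	up	SCD	let-7d-5p
ERalpha	up	RSBN1	miR-20b-5p;miR-31-5p;miR-520d-3p;miR-520e
ERalpha	up	ARHGAP17	miR-101-3p
LSD1	up	MAP2K7	miR-142-5p
LSD1	up	MYH10	miR-300
LSD1	up	NAP1L1	let-7d-5p;miR-101-3p;miR-148a-3p
LSD1	up	TFRC	miR-144-3p;miR-148a-3p;miR-31-5p;miR-758-3p
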