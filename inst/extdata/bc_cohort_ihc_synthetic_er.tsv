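patient_id	cytology	histology	grade	staging	pr_raw	pr_pct	her2_score	er_group	er_pct	ki67_pct
PT1	C5	Invasive carcinoma of no special type (NST)	G2	pT1N0	70	70	3	positive	80	NA
PT2		Invasive carcinoma of no special type (NST)	G2	pT1N0	70	70	0	positive	80	NA
PT3		Invasive carcinoma of no special type (NST)	G3	pT2N2	60	60	1	positive	80	NA
PT4		Invasive carcinoma of no special type (NST)	G3	pT4bN0	0	0	3	negative	0	NA
PT5		Invasive carcinoma of no special type (NST)	G2	pT1N1a	0.8	0.8	1	positive	80	NA
PT6		Invasive carcinoma of no special type (NST)	G3	pT4bN2a	0.65	0.65	1	positive	80	NA
PT7		Invasive carcinoma of no special type (NST)	G2	pT2N1a	0	0	0	negative	0	NA
PT8		Invasive apocrine carcinoma (IAC)	G3	pT2N1a	0	0	3	negative	0	NA
PT9		Invasive mucinous carcinoma (IMC)	G2	pT1cN0	0.7	0.7	0	positive	80	NA
PT10		Invasive Ductal Carcinoma (IDC)	G1	pT2N0	0.03	0.03	0	positive	80	NA
PT11		Invasive carcinoma of no special type (NST)	G2	pT2N1	0.9	0.9	1	positive	80	NA
PT12		Invasive Ductal Carcinoma (IDC)	G3	pT2N0	0.7	0.7	1	positive	80	NA
PT13		Invasive Ductal Carcinoma (IDC)	G2	pT1cN0	0	0	0	negative	0	NA
PT14		Invasive Ductal Carcinoma (IDC)	G3	pT1bN1a	0	0	2	negative	0	NA
PT15		Invasive Ductal Carcinoma (IDC)	G2	pT2N2	<5	4	1	positive	80	NA
PT16		Invasive Ductal Carcinoma (IDC)	G2	pT1cN0	0.8	0.8	1	positive	80	NA
PT17		Invasive Ductal Carcinoma (IDC)	G2	pT1cN0	0.6	0.6	0	positive	80	NA
PT18		Invasive Ductal Carcinoma (IDC)	G2	pT2N1M1 (bone)	0.7	0.7	0	positive	80	NA
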