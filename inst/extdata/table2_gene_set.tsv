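gene	rbbh	phylomedb_id	ontology
LOC100890987	N/A	Phy00E9VCL_STRPU	N/A
LOC100891212	N/A	Phy00E9NDK_STRPU	N/A
LOC577463	N/A	Phy000VU63_STRPU*	GO:0005515
LOC577943	N/A	Phy00E9SJD_STRPU	N/A
LOC578009	N/A	Phy000VM39_STRPU*	N/A
LOC578017	N/A	Phy00E9SMM_STRPU	N/A
LOC582352	N/A	Phy00E9ZEJ_STRPU	N/A
LOC762881	C3YW32_BRAFL	Phy000VNKZ_STRPU*	N/A
LOC100893267_iso_X1	C3YI62_BRAFL	Phy00E9SFI_STRPU	GO:0031262, GO:0051315
LOC100888903	A7S6U8_NEMVE	Phy00EA5U1_STRPU	N/A
LOC100891350	A7SDT1_NEMVE	Phy00EA8QT_STRPU*	GO:0005509
LOC580808	A7S7R1_NEMVE	Phy0037CV2_STRPU*	N/A
LOC577313	F6REZ6_CIOIN	Phy00EAAOU_STRPU	N/A
LOC578221	C3ZA97_BRAFL	Phy000VYP2_STRPU*	N/A
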