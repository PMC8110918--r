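cell_type	gene	provenance	parent
B cells	BLK	in_panel
B cells	CD19	in_panel
B cells	MS4A1	in_panel
B cells	TNFRSF17	in_panel
B cells	FCRL2	not_in_panel
B cells	KIAA0125	not_in_panel
B cells	PNOC	not_in_panel
B cells	SPIB	not_in_panel
B cells	TCL1A	not_in_panel
Cytotoxic cells	GZMA	in_panel
Cytotoxic cells	GZMB	in_panel
Cytotoxic cells	GZMH	in_panel
Cytotoxic cells	KLRB1	in_panel
Cytotoxic cells	KLRD1	in_panel
Cytotoxic cells	KLRK1	in_panel
Cytotoxic cells	PRF1	in_panel
Cytotoxic cells	CTSW	in_panel
Cytotoxic cells	GNLY	in_panel
Cytotoxic cells	NKG7	not_in_panel
Dendritic cells	CCL13	in_panel
Dendritic cells	CD209	in_panel
Dendritic cells	HSD11B1	in_panel
Macrophages	CD163	in_panel
Macrophages	CD68	in_panel
Macrophages	CD84	in_panel
Macrophages	MS4A4A	not_in_panel
Mast cells	MS4A2	in_panel
Mast cells	TPSAB1	in_panel
Mast cells	CPA3	not_in_panel
Mast cells	HDC	not_in_panel
Mast cells	TPSB2	not_in_panel
Natural Killer cells	NCR1	in_panel
Natural Killer cells	XCL1	not_in_panel
Natural Killer cells	XCL2	in_panel
Natural Killer CD56+ dim cells	IL21R	in_panel
Natural Killer CD56+ dim cells	KIR3DL1	in_panel
Natural Killer CD56+ dim cells	KIR2DL3	in_panel
Natural Killer CD56+ dim cells	KIR3DL2	in_panel
Neutrophils	CEACAM3	not_in_panel
Neutrophils	CSF3R	in_panel
Neutrophils	FCAR	not_in_panel
Neutrophils	FCGR3B	not_in_panel
Neutrophils	FPR1	not_in_panel
Neutrophils	S100A12	in_panel
Neutrophils	SIGLEC5	not_in_panel
T cells	CD3D	in_panel
T cells	CD3E	in_panel
T cells	CD3G	in_panel
T cells	CD6	in_panel
T cells	SH2D1A	in_panel
T cells	TRAT1	not_in_panel
CD8+ T cells	CD8A	in_panel	T cells
CD8+ T cells	CD8B	in_panel	T cells
Exhausted CD8+ T cells	CD244	in_panel	CD8+ T cells
Exhausted CD8+ T cells	EOMES	in_panel	CD8+ T cells
Exhausted CD8+ T cells	LAG3	in_panel	CD8+ T cells
Exhausted CD8+ T cells	PTGER4	in_panel	CD8+ T cells
Helper 1 T cells	TBX21	in_panel	T cells
Regulatory T cells	FOXP3	in_panel	T cells
CD45+	PTPRC	in_panel
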