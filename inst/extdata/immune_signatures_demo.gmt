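B_cells	curated marker panel	CD19	MS4A1	CD79A	CD79B	BLK	TNFRSF13B
CD8_T_cells	curated marker panel	CD8A	CD8B	GZMK	GZMA	PRF1	CD3D	CD3E
NK_cells	curated marker panel	NKG7	KLRD1	KLRF1	NCR1	GNLY	KIR2DL3
Macrophages	curated marker panel	CD68	CD163	MSR1	MRC1	CSF1R	ITGAM
Neutrophils	curated marker panel	FCGR3B	CEACAM3	CSF3R	S100A12	FPR1
Dendritic_cells	curated marker panel	CD1C	CLEC4C	BATF3	FLT3	ITGAX
Th1_cells	curated marker panel	TBX21	IFNG	IL12RB2	STAT4	CXCR3
Th2_cells	curated marker panel	GATA3	IL4	IL5	IL13	CCR4	STAT6
Mast_cells	curated marker panel	TPSAB1	TPSB2	CPA3	MS4A2	KIT
Endothelial_cells	curated marker panel	PECAM1	VWF	CDH5	CLDN5	TEK
Fibroblasts	curated marker panel	COL1A1	COL1A2	COL3A1	DCN	LUM	FAP
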