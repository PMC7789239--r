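aDC	immune_cell_markers	CCL1	EBI3	IDO1	LAMP3	OAS3
B_cells	immune_cell_markers	CD19	MS4A1	CD79A	CD79B	BLK	TNFRSF17	FCRL2
CD8_T_cells	immune_cell_markers	CD8A	CD8B	GZMM	PRF1	FLT3LG
Cytotoxic_cells	immune_cell_markers	GZMA	GZMB	GZMH	KLRB1	KLRD1	KLRK1	NKG7	CTSW	GNLY
DC	immune_cell_markers	CCL13	CD209	HSD11B1	NPR1	PPFIBP2
Eosinophils	immune_cell_markers	IL5RA	CCR3	EPX	GALC	PRG2	SIGLEC8
iDC	immune_cell_markers	CD1A	CD1B	CD1C	CD1E	F13A1	SYT17
Macrophages	immune_cell_markers	CD68	CD163	MSR1	MRC1	MARCO	CXCL5	SULT1C2
Mast_cells	immune_cell_markers	TPSAB1	TPSB2	CPA3	MS4A2	CMA1	KIT	HDC
Neutrophils	immune_cell_markers	FPR1	FCGR3B	CSF3R	S100A12	CEACAM3	SIGLEC5
NK_CD56bright_cells	immune_cell_markers	XCL1	XCL2	NCAM1	KIR2DL5A	PLA2G6
NK_CD56dim_cells	immune_cell_markers	KIR2DL3	KIR3DL1	KIR2DS1	IL21R	SPON2
NK_cells	immune_cell_markers	NCR1	NCR3	KLRF1	KLRC3	SLC30A5
pDC	immune_cell_markers	IL3RA	CLEC4C	LILRA4	PTCRA	TLR9
T_cells	immune_cell_markers	CD2	CD3D	CD3E	CD3G	CD6	TRAC	SH2D1A
T_helper_cells	immune_cell_markers	CD4	ICOS	ITM2A	CD28
Tcm	immune_cell_markers	CCR7	SELL	AQP3	TRAT1
Tem	immune_cell_markers	CCR5	GZMK	TBC1D4	DUSP4
TFH	immune_cell_markers	CXCR5	BCL6	MAF	PDCD1	CD200
Tgd	immune_cell_markers	TRGC1	TRGC2	TRDC
Th1_cells	immune_cell_markers	TBX21	IFNG	IL12RB2	STAT4	CXCR3
Th2_cells	immune_cell_markers	GATA3	IL4	IL5	IL13	CCR4	STAT6
Th17_cells	immune_cell_markers	RORC	IL17A	IL17RA	CCR6	IL23R
Treg	immune_cell_markers	FOXP3	IL2RA	CTLA4	IKZF2	TNFRSF18
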