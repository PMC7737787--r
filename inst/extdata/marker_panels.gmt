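T	T-cell markers	CD2	CD3D	CD3E	CD3G
B	B-cell markers	CD19	MS4A1	CD79A	CD79B
monocyte	monocyte markers	CD14	CD68	CD163
leukocyte	pan-leukocyte marker	PTPRC
lung	lung/LUAD origin markers	SFTPA1	SFTPA2	SFTPB	NAPSA
epithelial	epithelial markers	EPCAM	CDH1	KRT7	KRT8	KRT18	MUC1
proliferation	proliferation markers	CCND1	TOP2A
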