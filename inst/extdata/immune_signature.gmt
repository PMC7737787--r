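immune_signature	package-curated immune signature (T/NK/monocyte/B/MHC-II markers); override via GMT	PTPRC	CD2	CD3D	CD3E	CD3G	CD8A	CD8B	CD4	IL7R	CCL5	NKG7	GNLY	GZMA	GZMB	GZMK	PRF1	KLRB1	KLRD1	CD14	CD68	CD163	LYZ	FCGR3A	FCN1	S100A8	S100A9	CSF1R	ITGAM	CD19	MS4A1	CD79A	CD79B	CD37	HLA-DRA	HLA-DRB1	HLA-DPA1	HLA-DPB1	CIITA	CXCR4	CCR7	IL2RB	IL2RG	LCK	ZAP70	LAT	CD27	CD28	CTLA4	TIGIT	CD52
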