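T cell receptor signaling pathway (hsa04660)	KEGG immune system; synthetic reduced member list	CD3D	CD3E	CD3G	CD247	CD4	CD8A	LCK	ZAP70	LAT	ITK	FYN	PLCG1	CD28	CTLA4	RASGRP1	CBLB
Th1 and Th2 cell differentiation (hsa04658)	KEGG immune system; synthetic reduced member list	GATA3	TBX21	STAT1	STAT4	STAT6	IL4R	IFNGR1	CD3D	CD3E	LAT	RUNX3	MAML1
Th17 cell differentiation (hsa04659)	KEGG immune system; synthetic reduced member list	RORA	RORC	STAT3	IL17A	IL21	IL23R	SMAD2	HSP90AA1	CD3E	CD4	LAT	IL1B
B cell receptor signaling pathway (hsa04662)	KEGG immune system; synthetic reduced member list	CD19	CD79A	CD79B	BLNK	BTK	SYK	LYN	PIK3CA	CD22	CR2	PLCG2	RASGRP3
Intestinal immune network for IgA production (hsa04672)	KEGG immune system; synthetic reduced member list	TGFB1	IL10	IL15	AICDA	CD40	CD40LG	ITGA4	ITGB7	MADCAM1	CCL28	CXCR4	IL6
Antigen processing and presentation (hsa04612)	KEGG immune system; synthetic reduced member list	HLA-A	HLA-B	HLA-C	HLA-DRA	HLA-DRB1	TAP1	TAP2	B2M	PSME1	CTSS	CD74	KLRD1	HSPA8
Natural killer cell mediated cytotoxicity (hsa04650)	KEGG immune system; synthetic reduced member list	KLRD1	KLRK1	NCR1	NCR2	NCR3	PRF1	GZMB	FCGR3A	KIR2DL1	SH2D1A	LCK	FYN	ITGB2	ICAM1
Complement and coagulation cascades (hsa04610)	KEGG immune system; synthetic reduced member list	C3	C5	C6	C7	C9	CR2	F2	F11	FGG	SERPINE1	SERPIND1	PLAT	PLAU	CFH
Platelet activation (hsa04611)	KEGG immune system; synthetic reduced member list	GP5	GP9	GP1BA	ITGA2B	ITGB3	COL1A1	COL3A1	ADCY6	MYLK4	F2R	FGG	PLCB1	PRKACA
Hematopoietic cell lineage (hsa04640)	KEGG immune system; synthetic reduced member list	CD34	CD38	KIT	CSF1R	CSF2RA	CSF3R	EPOR	FLT3	IL3RA	IL7R	MS4A1	CD19	CD2	CD5	ANPEP
Toll-like receptor signaling pathway (hsa04620)	KEGG immune system; synthetic reduced member list	TLR1	TLR2	TLR4	TLR8	MYD88	IRAK1	IRAK4	TRAF6	TICAM1	CD14	LY96	MAPK14	IRF7	CXCL8
Toll and Imd signaling pathway (hsa04624)	KEGG immune system; synthetic reduced member list	TRAF6	MYD88	RELA	NFKB1	IKBKB	IKBKG	MAP3K7	TAB1	TAB2	ATF2
NOD-like receptor signaling pathway (hsa04621)	KEGG immune system; synthetic reduced member list	NOD1	NOD2	NLRP3	NLRP12	NLRC4	CASP1	PYCARD	RIPK2	NFKB1	IL1B	IL18	GBP5	NAIP
RIG-I-like receptor signaling pathway (hsa04622)	KEGG immune system; synthetic reduced member list	DDX58	IFIH1	DHX58	MAVS	IRF3	IRF7	TBK1	IKBKE	TRAF3	ISG15	IFNB1	NFKB1
Cytosolic DNA-sensing pathway (hsa04623)	KEGG immune system; synthetic reduced member list	CGAS	TMEM173	ZBP1	AIM2	IFI16	IRF3	TBK1	IL1B	IL18	CASP1	POLR3A
C-type lectin receptor signaling pathway (hsa04625)	KEGG immune system; synthetic reduced member list	CLEC7A	CLEC4E	CLEC6A	FCER1G	SYK	CARD9	BCL10	MALT1	IL10	IL6	EGR2	NFATC1
Fc epsilon RI signaling pathway (hsa04664)	KEGG immune system; synthetic reduced member list	FCER1A	FCER1G	MS4A2	LYN	SYK	FYN	BTK	PLCG1	PRKCA	VAV1	PIK3CA	MAPK1	IL4	IL13
Fc gamma R-mediated phagocytosis (hsa04666)	KEGG immune system; synthetic reduced member list	FCGR1A	FCGR2A	FCGR3A	SYK	HCK	LYN	VAV1	RAC1	ARPC2	WAS	PIK3CA	PRKCA	PLA2G4A	DOCK2
Leukocyte transendothelial migration (hsa04670)	KEGG immune system; synthetic reduced member list	ICAM1	VCAM1	PECAM1	ESAM	JAM2	CLDN1	CXCR4	ITGAM	ITGB2	ITGA4	MYL2	VAV1	RAC1	NCF2	CYBB
Chemokine signaling pathway (hsa04062)	KEGG immune system; synthetic reduced member list	CCL2	CCL5	CXCL8	CXCL10	CCR2	CCR5	CXCR4	CX3CR1	GNAI2	JAK2	STAT3	PIK3CA	VAV1	HCK	NCF1	ADCY6
IL-17 signaling pathway (hsa04657)	KEGG immune system; synthetic reduced member list	IL17A	IL17RA	TRAF3IP2	TRAF6	NFKB1	MAPK14	CXCL8	CCL2	CSF3	MMP9	HSP90AA1	IL6
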