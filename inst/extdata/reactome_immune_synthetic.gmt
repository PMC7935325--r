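Hemostasis	Reactome; synthetic reduced member list	F2	F11	FGG	PLAT	PLAU	GP5	GP1BA	ITGA2B	ITGB3	SERPINE1	VWF
Platelet homeostasis	Reactome; synthetic reduced member list	ADCY6	PRKACA	GP5	GP9	PLCB1	ITPR3
Platelet adhesion to exposed collagen	Reactome; synthetic reduced member list	COL1A1	COL3A1	GP5	GP9	GP1BA	ITGA2B
Platelet activation, signaling and aggregation	Reactome; synthetic reduced member list	GP1BA	ITGA2B	ITGB3	F2R	PLCB1	VAV1	FGG	VWF
Formation of fibrin clot	Reactome; synthetic reduced member list	F2	F11	FGG	SERPIND1	PLAT	VWF	F13A1
Dissolution of fibrin clot	Reactome; synthetic reduced member list	PLAT	PLAU	SERPINE1	PLG	ANXA2
Cell surface interactions at the vascular wall	Reactome; synthetic reduced member list	PECAM1	ESAM	JAM2	ICAM1	VCAM1	ITGAM	ITGB2	SELL
Adaptive immune system	Reactome; synthetic reduced member list	CD3D	CD8A	LCK	ZAP70	LAT	ITK	CD19	BTK	HLA-A	HLA-DRA	CD74	CTLA4	CD28
Innate immune system	Reactome; synthetic reduced member list	TLR2	TLR4	NLRP3	DDX58	CLEC7A	FCGR1A	FCGR2A	NCF1	NCF2	CYBB	MYD88	CASP1
Cytokine signaling in immune system	Reactome; synthetic reduced member list	JAK2	STAT1	STAT3	STAT6	IL6	IL10	IL4R	IFNGR1	IL1B	IL18	CXCL10	IL7R
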