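activation of innate immune response	GO; synthetic reduced member list	TLR2	TLR4	MYD88	DDX58	NOD2	CGAS	TBK1	IRF3	CD14
innate immune response	GO; synthetic reduced member list	TLR4	NLRP3	CASP1	DDX58	IFI16	CLEC7A	MYD88	NCF2	CYBB	LY96
complement activation	GO; synthetic reduced member list	C3	C5	C6	C7	C9	CFH	CR2	MASP1	C1QA
immune response-activating signal transduction	GO; synthetic reduced member list	SYK	BTK	LYN	ZAP70	LCK	MYD88	TRAF6	PLCG1	PLCG2
adaptive immune response	GO; synthetic reduced member list	CD3D	CD3E	CD8A	CD247	ZAP70	ITK	LAT	CD19	CD79A	AICDA	CTLA4	GATA3
leukocyte homeostasis	GO; synthetic reduced member list	IL7R	KIT	FLT3	CSF1R	EPOR	CD34	FAS	BCL2
leukocyte activation	GO; synthetic reduced member list	CD28	CD40	CD40LG	ITGAM	ITGB2	VAV1	SYK	PRKCQ
leukocyte migration	GO; synthetic reduced member list	ICAM1	VCAM1	PECAM1	CXCR4	CCR2	CCL2	CCL5	ITGA4	MADCAM1	ESAM
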