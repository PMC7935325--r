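pathway	source	category
T cell receptor signaling pathway (hsa04660)	KEGG	adaptive immunity
Th1 and Th2 cell differentiation (hsa04658)	KEGG	adaptive immunity
Th17 cell differentiation (hsa04659)	KEGG	adaptive immunity
B cell receptor signaling pathway (hsa04662)	KEGG	adaptive immunity
Intestinal immune network for IgA production (hsa04672)	KEGG	adaptive immunity
Antigen processing and presentation (hsa04612)	KEGG	antigen presentation
Natural killer cell mediated cytotoxicity (hsa04650)	KEGG	NK cell activity
Complement and coagulation cascades (hsa04610)	KEGG	complement-coagulation
Platelet activation (hsa04611)	KEGG	platelet activity
Hematopoietic cell lineage (hsa04640)	KEGG	hematopoiesis
Toll-like receptor signaling pathway (hsa04620)	KEGG	innate immunity
Toll and Imd signaling pathway (hsa04624)	KEGG	innate immunity
NOD-like receptor signaling pathway (hsa04621)	KEGG	innate immunity
RIG-I-like receptor signaling pathway (hsa04622)	KEGG	innate immunity
Cytosolic DNA-sensing pathway (hsa04623)	KEGG	innate immunity
C-type lectin receptor signaling pathway (hsa04625)	KEGG	innate immunity
Fc epsilon RI signaling pathway (hsa04664)	KEGG	signaling
Fc gamma R-mediated phagocytosis (hsa04666)	KEGG	signaling
Leukocyte transendothelial migration (hsa04670)	KEGG	leukocyte migration
Chemokine signaling pathway (hsa04062)	KEGG	cytokines-chemokines
IL-17 signaling pathway (hsa04657)	KEGG	cytokines-chemokines
activation of innate immune response	GO	innate immunity
innate immune response	GO	innate immunity
complement activation	GO	complement-coagulation
immune response-activating signal transduction	GO	signaling
adaptive immune response	GO	adaptive immunity
leukocyte homeostasis	GO	hematopoiesis
leukocyte activation	GO	signaling
leukocyte migration	GO	leukocyte migration
Hemostasis	Reactome	complement-coagulation
Platelet homeostasis	Reactome	platelet activity
Platelet adhesion to exposed collagen	Reactome	platelet activity
Platelet activation, signaling and aggregation	Reactome	platelet activity
Formation of fibrin clot	Reactome	complement-coagulation
Dissolution of fibrin clot	Reactome	complement-coagulation
Cell surface interactions at the vascular wall	Reactome	leukocyte migration
Adaptive immune system	Reactome	adaptive immunity
Innate immune system	Reactome	innate immunity
Cytokine signaling in immune system	Reactome	cytokines-chemokines
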