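gene	allele_label	markers	gene_alleles	provisional	provenance
IGKC	Km3	Km3	IGKC*01,IGKC*02,IGKC*03,IGKC*05	no	t_km
IGKC	Km1,2	Km1,2	IGKC*04	no	t_km
IGKC	Km1	Km1	IGKC*06	no	t_km
IGHG1	G1m17,1	G1m17;G1m1	IGHG1*01,IGHG1*02,IGHG1*05	no	t14
IGHG1	G1m3	G1m3	IGHG1*03	no	t14
IGHG1	G1m17,1,27	G1m17;G1m1;G1m27	IGHG1*04	no	t14
IGHG1	G1m17,1,28	G1m17;G1m1;G1m28	IGHG1*05p	yes	t14
IGHG1	G1m17,1,27,28	G1m17;G1m1;G1m27;G1m28	IGHG1*06p	yes	t14
IGHG1	G1m17,1,2	G1m17;G1m1;G1m2	IGHG1*07p	yes	t14
IGHG1	G1m3,1	G1m3;G1m1	IGHG1*08p	yes	t14
IGHG3	G3m5*	G3m5;G3m10;G3m11;G3m13;G3m14;G3m26;G3m27	IGHG3*01	no	t_g3m
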