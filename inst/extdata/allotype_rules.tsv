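marker	type	gene	domain	position	aa	provenance
Km3	allele	IGKC	CL	45.1	A	t_km
Km3	allele	IGKC	CL	101	V	t_km
Km1,2	allele	IGKC	CL	45.1	A	t_km
Km1,2	allele	IGKC	CL	101	L	t_km
Km1	allele	IGKC	CL	45.1	V	t_km
Km1	allele	IGKC	CL	101	L	t_km
Mcg+	isotype_marker	IGLC	CL	1	N	t_igl
Mcg+	isotype_marker	IGLC	CL	3	T	t_igl
Mcg-	isotype_marker	IGLC	CL	1	A	t_igl
Mcg-	isotype_marker	IGLC	CL	3	S	t_igl
Ke+	isotype_marker	IGLC	CL	45	G	t_igl
Ke-	isotype_marker	IGLC	CL	45	S	t_igl
Oz+	isotype_marker	IGLC	CL	100	K	t_igl
Oz-	isotype_marker	IGLC	CL	100	R	t_igl
G1m17	allotype	IGHG1	CH1	120	K	t14
G1m3	allotype	IGHG1	CH1	103	I	t14
G1m3	allotype	IGHG1	CH1	120	R	t14
nG1m17	isoallotype	IGHG1	CH1	120	R	t14
G1m1	allotype	IGHG1	CH3	12	D	t14
G1m1	allotype	IGHG1	CH3	14	L	t14
nG1m1	isoallotype	IGHG1	CH3	12	E	t14
nG1m1	isoallotype	IGHG1	CH3	14	M	t14
G1m27	allotype	IGHG1	CH3	101	I	t14
G1m2	allotype	IGHG1	CH3	110	G	t14
G1m28	allotype	IGHG1	CH3	115	R	t14
G1m28	allotype	IGHG1	CH3	116	Y	t14
G2m23	allotype	IGHG2	CH2	45.1	M	t_g2m
G3m16	allotype	IGHG3	CH2	83	W	t_g3m
G3m21	allotype	IGHG3	CH2	82	L	t_g3m
nG3m21	isoallotype	IGHG3	CH2	82	P	t_g3m
G3m11	allotype	IGHG3	CH3	44	S	t_g3m
nG3m11	isoallotype	IGHG3	CH3	44	N	t_g3m
G3m10	allotype	IGHG3	CH3	44	S	t_g3m
G3m10	allotype	IGHG3	CH3	101	I	t_g3m
G3m24	allotype	IGHG3	CH3	44	S	t_g3m
G3m24	allotype	IGHG3	CH3	101	V	t_g3m
G3m27	allotype	IGHG3	CH3	101	I	t_g3m
G3m6	allotype	IGHG3	CH3	44	S	t_g3m
G3m6	allotype	IGHG3	CH3	98	E	t_g3m
G3m13	allotype	IGHG3	CH3	44	S	t_g3m
G3m13	allotype	IGHG3	CH3	98	Q	t_g3m
G3m26	allotype	IGHG3	CH3	115	R	t_g3m
G3m5	allotype	IGHG3	CH3	115	R	t_g3m
G3m5	allotype	IGHG3	CH3	116	F	t_g3m
nG3m5	isoallotype	IGHG3	CH3	115	H	t_g3m
nG3m5	isoallotype	IGHG3	CH3	116	Y	t_g3m
G3m28	allotype	IGHG3	CH3	115	R	t_g3m
G3m28	allotype	IGHG3	CH3	116	Y	t_g3m
G3m14	allotype	IGHG3	CH3	84	M	t_g3m
G3m14	allotype	IGHG3	CH3	115	R	t_g3m
G3m14	allotype	IGHG3	CH3	116	F	t_g3m
G3m15	allotype	IGHG3	CH3	39	M	t_g3m
G3m15	allotype	IGHG3	CH3	115	H	t_g3m
G3m15	allotype	IGHG3	CH3	116	Y	t_g3m
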