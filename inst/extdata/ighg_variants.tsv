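gene	variant	changes	properties	provenance
IGHG1	IGHG1v1	CH2:P1.4	ADCC reduction	t15
IGHG1	IGHG1v2	CH2:V1.3	ADCC reduction	t15
IGHG1	IGHG1v3	CH2:A1.2	ADCC reduction	t15
IGHG1	IGHG1v4	CH2:A114	ADCC reduction; CDC reduction	t15
IGHG1	IGHG1v5	CH2:W109	ADCC reduction; CDC enhancement	t15
IGHG1	IGHG1v6	CH2:A85.4;CH2:A118;CH2:A119	ADCC enhancement	t15
IGHG1	IGHG1v7	CH2:D3;CH2:E117	ADCC enhancement	t15
IGHG1	IGHG1v8	CH2:D3;CH2:L115;CH2:E117	ADCC enhancement; CDC reduction	t15
IGHG1	IGHG1v9	CH2:L7;CH2:P83;CH2:L85.2;CH2:I88;CH3:L83	ADCC enhancement	t15
IGHG1	IGHG1v10	CH2:Y1.3;CH2:Q1.2;CH2:W1.1;CH2:M3;CH2:D30;CH2:E34;CH2:A85.4	ADCC enhancement	t15
IGHG1	IGHG1v11	CH2:E34;CH2:D109;CH2:M115;CH2:E119	ADCC enhancement	t15
IGHG1	IGHG1v12	CH2:A1.1;CH2:D3;CH2:L115;CH2:E117	ADCC enhancement	t15
IGHG1	IGHG1v13	CH2:A1.1;CH2:D3;CH2:E117	ADCP enhancement	t15
IGHG1	IGHG1v14	CH2:A1.3;CH2:A1.2	ADCC reduction; CDC reduction	t15
IGHG1	IGHG1v15	CH2:S118	CDC enhancement	t15
IGHG1	IGHG1v16	CH2:W109;CH2:S118	CDC enhancement	t15
IGHG1	IGHG1v17	CH2:E29;CH2:F30;CH2:T107	CDC enhancement	t15
IGHG1	IGHG1v18	CH3:R1;CH3:G109;CH3:Y120	CDC enhancement; favors hexamerisation	t15
IGHG1	IGHG1v19	CH2:A34	CDC reduction	t15
IGHG1	IGHG1v20	CH2:A105	CDC reduction	t15
IGHG1	IGHG1v21	CH2:Y15.1;CH2:T16;CH2:E18	half-life increase	t15
IGHG1	IGHG1v22	CH2:Y15.1;CH2:T16;CH2:E18;CH3:K113;CH3:F114;CH3:H116	half-life increase	t15
IGHG1	IGHG1v23	CH2:E1.2	ADCC reduction; CDC reduction	t15
IGHG1	IGHG1v24	CH3:L107;CH3:S114	half-life increase	t15
IGHG1	IGHG1v25	CH2:E29;CH2:F113	B cell inhibition	t15
IGHG1	IGHG1v26	CH3:Y22	knob in knobs-into-holes	t15
IGHG1	IGHG1v27	CH2:C3	site-specific drug attachment	t15
IGHG1	IGHG1v28	CH2:insC3A	site-specific drug attachment	t15
IGHG1	IGHG1v29	CH2:A84.4	no N-glycosylation site	t15
IGHG1	IGHG1v30	CH2:G84.4	no N-glycosylation site	t15
IGHG1	IGHG1v31	CH3:T86	hole in knobs-into-holes	t15
IGHG1	IGHG1v32	CH3:W22	knob in knobs-into-holes	t15
IGHG1	IGHG1v33	CH3:S22;CH3:A24;CH3:V86	hole in knobs-into-holes	t15
IGHG1	IGHG1v34	CH3:G109	favors hexamerisation	t15
IGHG1	IGHG1v35	CH2:E29	CDC enhancement	t15
IGHG1	IGHG1v36	CH2:Q84.4	no N-glycosylation site	t15
IGHG1	IGHG1v37	h:S5	no disulfide bridge inter H-L	t15
IGHG1	IGHG1v38	CH2:S108;CH2:F113	abrogation of FcgRIII binding; abrogation of C1q binding	t15
IGHG2	IGHG2v1	CH2:L1.3;CH2:L1.2;CH2:G1.1;CH2:G1	ADCC enhancement	t15
IGHG2	IGHG2v2	CH2:Q30;CH2:L92;CH2:S115;CH2:S116	ADCC reduction; CDC reduction	t15
IGHG2	IGHG2v3	CH2:A1.2;CH2:A1;CH2:S2;CH2:A30;CH2:L92;CH2:S115;CH2:S116	ADCC reduction; CDC reduction	t15
IGHG2	IGHG2v4	CH2:Q14	half-life increase	t15
IGHG2	IGHG2v5	CH3:L107	half-life increase	t15
IGHG2	IGHG2v6	CH2:Q14;CH3:L107	half-life increase	t15
IGHG3	IGHG3v1	CH3:H115	half-life increase	t15
IGHG4	IGHG4v1	CH2:L1.3	ADCC enhancement	t15
IGHG4	IGHG4v2	CH2:P116	CDC enhancement	t15
IGHG4	IGHG4v3	CH2:E1.2	ADCC reduction; CDC reduction	t15
IGHG4	IGHG4v4	CH2:A1.3;CH2:A1.2	ADCC reduction; CDC reduction	t15
IGHG4	IGHG4v5	h:P10	half-IG exchange reduction	t15
IGHG4	IGHG4v6	CH3:K88	half-IG exchange reduction	t15
IGHG4	IGHG4v21	CH2:Y15.1;CH2:T16;CH2:E18	half-life increase	t15
IGHG4	IGHG4v36	CH2:Q84.4	no N-glycosylation site	t15
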