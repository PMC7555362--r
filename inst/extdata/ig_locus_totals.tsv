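locus	group	genes_major	genes_orphon	alleles_major	alleles_orphon	provenance
IGH	IGHV	159	26	494	49	t5
IGH	IGHD	27	10	34	10	t5
IGH	IGHJ	9	0	19	0	t5
IGH	IGHC	11	1	91	2	t5
IGK	IGKV	77	32	114	34	t5
IGK	IGKJ	5	0	9	0	t5
IGK	IGKC	1	0	5	0	t5
IGL	IGLV	78	4	144	5	t5
IGL	IGLJ	11	0	10	0	t5
IGL	IGLC	11	3	21	4	t5
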