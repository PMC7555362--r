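domain	imgt	eu	provenance
h	5	220	t15
h	10	228	t15
CH2	1.4	233	t15
CH2	1.3	234	t15
CH2	1.2	235	t15
CH2	1.1	236	t15
CH2	1	237	t15
CH2	2	238	t15
CH2	3	239	t15
CH2	7	243	t15
CH2	14	250	t15
CH2	15.1	252	t15
CH2	16	254	t15
CH2	18	256	t15
CH2	29	267	t15
CH2	30	268	t15
CH2	34	270	t15
CH2	83	292	t15
CH2	84.4	297	t15
CH2	85.4	298	t15
CH2	85.2	300	t15
CH2	88	305	t15
CH2	92	309	t15
CH2	105	322	t15
CH2	107	324	t15
CH2	108	325	t15
CH2	109	326	t15
CH2	113	328	t15
CH2	114	329	t15
CH2	115	330	t15
CH2	116	331	t15
CH2	117	332	t15
CH2	118	333	t15
CH2	119	334	t15
CH3	1	345	t15
CH3	22	366	t15
CH3	24	368	t15
CH3	83	396	t15
CH3	86	407	t15
CH3	88	409	t15
CH3	107	428	t15
CH3	109	430	t15
CH3	113	433	t15
CH3	114	434	t15
CH3	115	435	t15
CH3	116	436	t15
CH3	120	440	t15
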